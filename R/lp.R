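# Linear-programming core. All flux-space problems in the package reduce to
#   optimize c'v  subject to  S v = 0,  lb <= v <= ub,
# with finite bounds (the +/-1000 sentinel makes every variable bounded).
# The problem is shifted to nonnegative variables x = v - lb and handed to
# the two-phase simplex in the recommended 'boot' package. Two
# preprocessing steps keep that solver on its well-behaved path: variables
# pinned by equal bounds are substituted out, and the equality system is
# row-reduced to an independent, consistent subset (conservation relations
# make rows of S linearly dependent, which the solver mishandles).

lp_flux <- function(S, lb, ub, objective, sense = c("max", "min"),
                    tol = 1e-9) {
  sense <- match.arg(sense)
  S <- as.matrix(S)
  n <- ncol(S)
  stopifnot(length(lb) == n, length(ub) == n, length(objective) == n)
  infeasible <- list(status = "infeasible", objective = NA_real_,
                     fluxes = rep(NA_real_, n))
  if (any(lb > ub)) return(infeasible)
  width <- ub - lb
  act <- which(width > 1e-12)
  b3_full <- as.numeric(-S %*% lb)
  Sa <- S[, act, drop = FALSE]

  if (length(act) == 0L) {
    if (length(b3_full) && max(abs(b3_full)) > 1e-6) return(infeasible)
    return(list(status = "optimal", objective = sum(objective * lb),
                fluxes = lb))
  }

  red <- rref(cbind(Sa, b3_full), tol = 1e-9)
  if (any(red$pivots == ncol(Sa) + 1L)) return(infeasible)
  R <- red$R[seq_along(red$pivots), , drop = FALSE]
  A3 <- R[, seq_len(ncol(Sa)), drop = FALSE]
  b3 <- R[, ncol(Sa) + 1L]
  sgn <- ifelse(b3 < 0, -1, 1)
  A3 <- A3 * sgn
  b3 <- b3 * sgn

  na <- length(act)
  obj_a <- objective[act]
  obj <- if (sense == "max") obj_a else -obj_a
  res <- tryCatch({
    if (nrow(A3) > 0L) {
      boot::simplex(a = obj, A1 = diag(na), b1 = width[act],
                    A3 = A3, b3 = b3, maxi = TRUE,
                    n.iter = 50 * (na + nrow(A3) + 10), eps = tol)
    } else {
      boot::simplex(a = obj, A1 = diag(na), b1 = width[act],
                    maxi = TRUE, n.iter = 50 * (na + 10), eps = tol)
    }
  }, error = function(e) NULL)
  if (is.null(res)) {
    return(list(status = "failed", objective = NA_real_,
                fluxes = rep(NA_real_, n)))
  }
  if (res$solved == -1) return(infeasible)
  if (res$solved != 1) {
    return(list(status = "failed", objective = NA_real_,
                fluxes = rep(NA_real_, n)))
  }
  v <- lb
  v[act] <- as.numeric(res$soln) + lb[act]
  list(status = "optimal", objective = sum(objective * v), fluxes = v)
}

# checks a flux vector against steady state and bounds; returns TRUE/FALSE
flux_is_valid <- function(S, v, lb, ub, balance_tol = 1e-6,
                          bound_tol = 1e-9) {
  max(abs(as.numeric(S %*% v))) <= balance_tol &&
    all(v >= lb - bound_tol) && all(v <= ub + bound_tol)
}
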