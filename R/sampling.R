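#' Project the flux polytope onto its independent variables
#'
#' Row-reduces the stoichiometric matrix to split the reactions into
#' dependent (pivot) and independent (free) coordinates: any assignment to
#' the free coordinates determines the dependent ones through the linear
#' map recorded in `dependency`, and the reconstructed vector satisfies
#' S v = 0 exactly up to round-off. This turns the (lower-dimensional)
#' steady-state polytope into a full-dimensional object over the free
#' coordinates, the space in which the samplers operate.
#'
#' Reactions whose bounds pin them to a single value (fixed maintenance
#' fluxes, measured uptake rates imposed as equalities) are folded into the
#' linear system as additional equations, so the projection is affine:
#' `v[pivot] = offset + D %*% v[free]`.
#'
#' @param model a `metabolic_model`.
#' @return list with `free` and `pivot` (reaction-id character vectors),
#'   `dependency` (matrix D), `offset` (numeric, one entry per pivot), and
#'   `dimension` (number of free coordinates). A model whose polytope is a
#'   single point has `dimension = 0`.
#' @export
project_to_independent_variables <- function(model) {
  S <- as.matrix(build_S(model))
  n <- ncol(S)
  ids <- model$reactions$id
  fixed <- which(model$reactions$lb == model$reactions$ub)
  A <- S
  b <- rep(0, nrow(S))
  if (length(fixed)) {
    E <- matrix(0, length(fixed), n)
    E[cbind(seq_along(fixed), fixed)] <- 1
    A <- rbind(A, E)
    b <- c(b, model$reactions$lb[fixed])
  }
  red <- rref(cbind(A, b))
  if (any(red$pivots == n + 1L)) {
    stop("inconsistent constraints: the flux polytope is empty",
         call. = FALSE)
  }
  piv <- red$pivots
  free <- setdiff(seq_len(n), piv)
  # row i of the reduced system reads v[piv[i]] + R[i, free] v[free] = b_i
  R <- red$R[seq_along(piv), , drop = FALSE]
  D <- -R[, free, drop = FALSE]
  offset <- R[, n + 1L]
  dimnames(D) <- list(ids[piv], ids[free])
  names(offset) <- ids[piv]
  list(free = ids[free], pivot = ids[piv], dependency = D,
       offset = offset, dimension = length(free))
}

# reduced row echelon form with partial pivoting; returns the reduced
# matrix and the pivot column indices
rref <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    sub <- abs(A[row:m, col])
    imax <- which.max(sub)
    if (sub[imax] <= tol) next
    ip <- row + imax - 1L
    if (ip != row) A[c(row, ip), ] <- A[c(ip, row), ]
    A[row, ] <- A[row, ] / A[row, col]
    others <- setdiff(seq_len(m), row)
    A[others, ] <- A[others, ] - outer(A[others, col], A[row, ])
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(R = A, pivots = pivots)
}

# reconstruct full flux vectors (rows) from free-coordinate rows Z
fluxes_from_free <- function(proj, Z, rxn_ids) {
  if (!is.matrix(Z)) Z <- matrix(Z, ncol = length(proj$free))
  V <- matrix(0, max(nrow(Z), 1L), length(rxn_ids),
              dimnames = list(NULL, rxn_ids))
  V[, proj$free] <- Z
  if (length(proj$pivot)) {
    V[, proj$pivot] <- sweep(Z %*% t(proj$dependency), 2, proj$offset,
                             "+")
  }
  V
}

new_flux_sample_set <- function(samples, condition, seed, sampler) {
  structure(list(samples = samples, condition = condition, seed = seed,
                 sampler = sampler, n = nrow(samples)),
            class = "flux_sample_set")
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat("Flux sample set:", x$n, "points x", ncol(x$samples),
      "reactions (", x$sampler, ", seed", x$seed, ")\n")
  invisible(x)
}

#' Uniform flux sampling by rejection (reference sampler)
#'
#' The literal low-dimensional method: the free coordinates are drawn
#' uniformly over their bounding box, the dependent fluxes are
#' back-calculated from the stoichiometric dependencies, and a draw is kept
#' only if the full vector violates no bound. Exact but collapses as
#' dimension grows, so it is guarded to polytopes of dimension at most 6
#' and serves as the reference against which the scalable sampler is
#' checked.
#'
#' @param model a `metabolic_model` (apply the condition first).
#' @param n number of valid points to return.
#' @param seed integer seed; the returned set is bitwise reproducible.
#' @param condition label stored with the sample.
#' @param max_dim dimension guard (default 6).
#' @return a `flux_sample_set` whose `samples` matrix is n x n_reactions.
#' @export
rejection_sample <- function(model, n, seed = 1L, condition = "default",
                             max_dim = 6L) {
  proj <- project_to_independent_variables(model)
  d <- proj$dimension
  if (d > max_dim) {
    stop("polytope dimension ", d, " exceeds the rejection-sampler guard (",
         max_dim, "); use hit_and_run_sample()", call. = FALSE)
  }
  rxn_ids <- model$reactions$id
  lb <- stats::setNames(model$reactions$lb, rxn_ids)
  ub <- stats::setNames(model$reactions$ub, rxn_ids)
  if (d == 0L) {
    V <- fluxes_from_free(proj, matrix(0, 1, 0), rxn_ids)
    if (!all(V[1, ] >= lb - 1e-9 & V[1, ] <= ub + 1e-9)) {
      stop("point polytope violates bounds: model infeasible",
           call. = FALSE)
    }
    return(new_flux_sample_set(V[rep(1L, n), , drop = FALSE], condition,
                               seed, "rejection"))
  }
  # tight bounding box of the independent variables: the achievable
  # flux range of each free coordinate, not the +/-1000 sentinels
  S <- build_S(model)
  lo <- numeric(d); hi <- numeric(d)
  for (jj in seq_len(d)) {
    j <- rxn_index(model, proj$free[jj])
    obj <- numeric(length(rxn_ids)); obj[j] <- 1
    lo_res <- lp_flux(S, model$reactions$lb, model$reactions$ub, obj,
                      sense = "min")
    hi_res <- lp_flux(S, model$reactions$lb, model$reactions$ub, obj,
                      sense = "max")
    if (lo_res$status != "optimal" || hi_res$status != "optimal") {
      stop("cannot bound free coordinate ", proj$free[jj],
           ": model infeasible", call. = FALSE)
    }
    lo[jj] <- lo_res$objective; hi[jj] <- hi_res$objective
  }
  set.seed(seed)
  kept <- matrix(NA_real_, 0, length(rxn_ids))
  attempts <- 0L
  while (nrow(kept) < n) {
    batch <- max(1000L, 2L * n)
    Z <- matrix(stats::runif(batch * d, rep(lo, each = batch),
                             rep(hi, each = batch)), batch, d)
    V <- fluxes_from_free(proj, Z, rxn_ids)
    ok <- rowSums(sweep(V, 2, lb, "<") | sweep(V, 2, ub, ">")) == 0L
    kept <- rbind(kept, V[ok, , drop = FALSE])
    attempts <- attempts + batch
    if (attempts >= 5e5 && nrow(kept) / attempts < 1e-6) {
      stop("rejection sampling acceptance rate below 1e-6 after ",
           attempts, " draws; polytope too thin in its bounding box",
           call. = FALSE)
    }
  }
  colnames(kept) <- rxn_ids
  new_flux_sample_set(kept[seq_len(n), , drop = FALSE], condition, seed,
                      "rejection")
}

#' Uniform flux sampling by coordinate hit-and-run (production sampler)
#'
#' A Gibbs-style walk over the free coordinates of the projected polytope:
#' at each step one coordinate is redrawn uniformly from the exact interval
#' the remaining constraints allow it, so every iterate is feasible and the
#' chain's stationary distribution is uniform on the polytope. The start is
#' the average of the flux vectors that individually minimize and maximize
#' each free coordinate (a feasible point by convexity). Warm-up iterations
#' are discarded and the chain is thinned.
#'
#' @inheritParams rejection_sample
#' @param warmup single-coordinate updates discarded before recording.
#' @param thinning updates between recorded points.
#' @return a `flux_sample_set`; rows satisfy S v = 0 within 1e-6 and the
#'   bounds within 1e-9 (asserted before returning).
#' @export
hit_and_run_sample <- function(model, n, seed = 1L, condition = "default",
                               warmup = 1000L, thinning = 10L) {
  proj <- project_to_independent_variables(model)
  d <- proj$dimension
  rxn_ids <- model$reactions$id
  lb <- stats::setNames(model$reactions$lb, rxn_ids)
  ub <- stats::setNames(model$reactions$ub, rxn_ids)
  S <- build_S(model)
  if (d == 0L) {
    V <- fluxes_from_free(proj, matrix(0, 1, 0), rxn_ids)
    if (!all(V[1, ] >= lb - 1e-9 & V[1, ] <= ub + 1e-9)) {
      stop("no feasible point: model infeasible", call. = FALSE)
    }
    return(new_flux_sample_set(V[rep(1L, n), , drop = FALSE], condition,
                               seed, "hit_and_run"))
  }
  z0 <- har_start(model, proj, S)
  D <- proj$dependency
  lbp <- lb[proj$pivot]; ubp <- ub[proj$pivot]
  lbf <- lb[proj$free]; ubf <- ub[proj$free]

  set.seed(seed)
  z <- z0
  w <- if (length(proj$pivot)) {
    proj$offset + as.numeric(D %*% z)
  } else {
    numeric(0)
  }
  keep <- matrix(NA_real_, n, d)
  total <- warmup + n * thinning
  coords <- sample.int(d, total, replace = TRUE)
  unif <- stats::runif(total)
  recorded <- 0L
  for (t in seq_len(total)) {
    j <- coords[t]
    lo <- lbf[j]; hi <- ubf[j]
    if (length(w)) {
      dj <- D[, j]
      act <- which(dj != 0)
      if (length(act)) {
        # w_i = D[i,-j] z[-j] + dj_i z_j must stay in [lbp_i, ubp_i]
        base <- w[act] - dj[act] * z[j]
        lo_i <- (lbp[act] - base) / dj[act]
        hi_i <- (ubp[act] - base) / dj[act]
        neg <- dj[act] < 0
        tmp <- lo_i[neg]; lo_i[neg] <- hi_i[neg]; hi_i[neg] <- tmp
        lo <- max(lo, max(lo_i))
        hi <- min(hi, min(hi_i))
      }
    }
    if (hi < lo) { # numeric corner: keep the current value
      znew <- z[j]
    } else {
      znew <- lo + unif[t] * (hi - lo)
    }
    if (length(w)) w <- w + D[, j] * (znew - z[j])
    z[j] <- znew
    if (t > warmup && (t - warmup) %% thinning == 0L) {
      recorded <- recorded + 1L
      keep[recorded, ] <- z
    }
  }
  V <- fluxes_from_free(proj, keep, rxn_ids)
  bal <- max(abs(as.matrix(S %*% t(V))))
  if (bal > 1e-6) {
    stop("sampled points violate steady state (max |S v| = ", bal, ")",
         call. = FALSE)
  }
  if (min(sweep(V, 2, lb, "-")) < -1e-9 ||
      max(sweep(V, 2, ub, "-")) > 1e-9) {
    stop("sampled points violate bounds beyond 1e-9", call. = FALSE)
  }
  new_flux_sample_set(V, condition, seed, "hit_and_run")
}

# feasible starting point: average of the flux vectors optimizing each
# free coordinate in both senses
har_start <- function(model, proj, S) {
  lb <- model$reactions$lb; ub <- model$reactions$ub
  n <- length(lb)
  acc <- numeric(n)
  cnt <- 0L
  for (id in proj$free) {
    j <- rxn_index(model, id)
    obj <- numeric(n); obj[j] <- 1
    for (sense in c("max", "min")) {
      res <- lp_flux(S, lb, ub, obj, sense = sense)
      if (res$status != "optimal") {
        stop("no feasible point found while seeding the sampler (", id,
             ", ", sense, ": ", res$status, ")", call. = FALSE)
      }
      acc <- acc + res$fluxes
      cnt <- cnt + 1L
    }
  }
  v0 <- acc / cnt
  v0[match(proj$free, model$reactions$id)]
}

#' Glucose-normalized median fluxes
#'
#' Column medians of a flux sample, divided by the absolute median flux of
#' the normalizing exchange (typically the condition's glucose uptake), the
#' scale on which flux maps are drawn and compared across salinities. The
#' normalizing exchange itself maps to -1 under the outward-positive
#' convention.
#'
#' @param sample a `flux_sample_set`.
#' @param normalize_by reaction id of the normalizing exchange.
#' @return named numeric vector of normalized medians.
#' @export
median_fluxes <- function(sample, normalize_by) {
  stopifnot(inherits(sample, "flux_sample_set"))
  if (!normalize_by %in% colnames(sample$samples)) {
    stop("unknown reaction id: ", normalize_by, call. = FALSE)
  }
  med <- apply(sample$samples, 2, stats::median)
  g <- med[[normalize_by]]
  if (abs(g) < 1e-12) {
    stop("median flux of ", normalize_by,
         " is zero; cannot normalize", call. = FALSE)
  }
  med / abs(g)
}
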