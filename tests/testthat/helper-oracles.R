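# Independent oracles: brute-force or closed-form computations kept
# deliberately separate from the implementation paths they check.

# LP optimum by basic-solution enumeration: every vertex of
# {S v = 0 (plus fixed bounds), lb <= v <= ub} has at least n - rank(S)
# coordinates at a bound; enumerate all such assignments and solve for
# the rest.
oracle_lp_vertex <- function(S, lb, ub, obj, sense = "max") {
  S <- as.matrix(S)
  n <- ncol(S)
  r <- qr(S)$rank
  k <- n - r
  best <- NA_real_
  better <- if (sense == "max") function(a, b) a > b else
    function(a, b) a < b
  subsets <- if (k == 0) list(integer(0)) else
    asplit(utils::combn(n, k), 2)
  for (F_idx in subsets) {
    F_idx <- as.integer(F_idx)
    B_idx <- setdiff(seq_len(n), F_idx)
    SB <- S[, B_idx, drop = FALSE]
    if (length(B_idx) && qr(SB)$rank < length(B_idx)) next
    n_assign <- 2^length(F_idx)
    for (mask in seq_len(max(n_assign, 1)) - 1L) {
      vF <- numeric(length(F_idx))
      for (t in seq_along(F_idx)) {
        vF[t] <- if (bitwAnd(mask, bitwShiftL(1L, t - 1L)) > 0)
          ub[F_idx[t]] else lb[F_idx[t]]
      }
      rhs <- if (length(F_idx))
        -S[, F_idx, drop = FALSE] %*% vF else matrix(0, nrow(S), 1)
      vB <- tryCatch(qr.solve(SB, rhs), error = function(e) NULL)
      if (is.null(vB)) next
      v <- numeric(n)
      v[F_idx] <- vF
      v[B_idx] <- vB
      if (max(abs(S %*% v)) > 1e-8) next
      if (any(v < lb - 1e-8) || any(v > ub + 1e-8)) next
      val <- sum(obj * v)
      if (is.na(best) || better(val, best)) best <- val
    }
  }
  best
}

# GPR truth-table oracle: substitute gene activity into the rule string
# and let R's parser (with its own and/or precedence) evaluate it.
oracle_gpr_eval <- function(rule, genes, knocked_out) {
  expr <- gsub("\\band\\b", "&", rule, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  for (g in genes) {
    expr <- gsub(paste0("\\b", g, "\\b"),
                 if (g %in% knocked_out) "FALSE" else "TRUE", expr)
  }
  eval(parse(text = expr))
}

# random GPR rule over the given gene names, as a string
random_gpr_rule <- function(genes, depth = 2) {
  if (depth == 0 || stats::runif(1) < 0.3) {
    return(sample(genes, 1))
  }
  op <- sample(c("and", "or"), 1)
  n_args <- sample(2:3, 1)
  args <- vapply(seq_len(n_args), function(i)
    random_gpr_rule(genes, depth - 1), character(1))
  paste0("(", paste(args, collapse = paste0(" ", op, " ")), ")")
}

# Spearman by explicit rank-then-Pearson arithmetic
oracle_spearman <- function(X) {
  R <- apply(X, 2, rank)
  p <- ncol(R)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(X),
                                                colnames(X)))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      xi <- R[, i] - mean(R[, i])
      xj <- R[, j] - mean(R[, j])
      out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  out
}

# BFS reachability oracle for blocked metabolites on unit-coefficient
# networks, matching the accumulation-allowed (relaxed) mass balance:
# a metabolite is producible if some directed reaction whose substrates
# are all already producible makes it; consumable if some directed
# reaction can consume it while its other substrates are producible.
oracle_blocked_bfs <- function(model) {
  for (id in exchange_reactions(model)) {
    model <- halofba:::set_bounds(model, id, lb = -1000, ub = 1000)
  }
  dirs <- list()
  for (i in seq_len(nrow(model$reactions))) {
    coefs <- model$stoichiometry[[i]]
    if (model$reactions$ub[i] > 0) {
      dirs[[length(dirs) + 1L]] <- list(
        subs = names(coefs)[coefs < 0], prods = names(coefs)[coefs > 0])
    }
    if (model$reactions$lb[i] < 0) {
      dirs[[length(dirs) + 1L]] <- list(
        subs = names(coefs)[coefs > 0], prods = names(coefs)[coefs < 0])
    }
  }
  P <- character(0)
  repeat {
    added <- FALSE
    for (d in dirs) {
      if (all(d$subs %in% P) && !all(d$prods %in% P)) {
        P <- union(P, d$prods)
        added <- TRUE
      }
    }
    if (!added) break
  }
  mets <- model$metabolites$id
  C <- mets[vapply(mets, function(x) {
    any(vapply(dirs, function(d) {
      x %in% d$subs && all(setdiff(d$subs, x) %in% P)
    }, logical(1)))
  }, logical(1))]
  list(no_production = setdiff(mets, P), no_consumption = setdiff(mets, C))
}
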