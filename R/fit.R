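## Maximum-likelihood fitting of the one-ratio model (M0) and the branch
## model (Mb: one omega per branch class), and the likelihood-ratio test.
##
## Optimisation strategy: coordinate cycles. Within a cycle every branch
## length is optimised by Brent's method using cached partial likelihoods
## ("inside" partials below each node, "outside" partials above each edge),
## then kappa and the omegas are refined jointly by bounded quasi-Newton
## (L-BFGS-B on the log scale). Cycles repeat until the log likelihood
## improves by less than `tol`.

.FIT_BOUNDS <- list(kappa = c(0.01, 20), omega = c(1e-4, 20),
                    blen = c(1e-8, 10))

## outside partials: for each non-root node v (child of u), the likelihood
## of all data outside v's subtree given the state at u, with pi applied at
## the root. Returns list(out = per-node matrices, outlog = log scalers).
.outside <- function(tree, pr, pi) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  edge <- tree$edge
  root <- nt + 1L
  out <- vector("list", nn)
  outlog <- numeric(nn)
  chmat <- function(v) if (v <= nt) pr$tipmats[[v]] else pr$down[[v]]
  chlog <- function(v) if (v <= nt) 0 else pr$logsc[[v]]
  ## preorder: parents before children
  ord <- rev(reorder_edges(tree))
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  for (e in ord) {
    u <- edge[e, 1]; v <- edge[e, 2]
    sib_edges <- setdiff(kids[[as.character(u)]], e)
    sib_term <- matrix(1, 61, ncol(pr$down[[root]]))
    sib_log <- 0
    for (se in sib_edges) {
      w <- edge[se, 2]
      sib_term <- sib_term * (pr$Pmats[[se]] %*% chmat(w))
      sib_log <- sib_log + chlog(w)
    }
    if (u == root) {
      out[[v]] <- pi * sib_term
      outlog[v] <- sib_log
    } else {
      out[[v]] <- (t(pr$Pmats[[e_in(tree, u)]]) %*% out[[u]]) * sib_term
      outlog[v] <- outlog[u] + sib_log
    }
    mx <- max(out[[v]])
    if (mx < 1e-80 && mx > 0) {
      out[[v]] <- out[[v]] / mx
      outlog[v] <- outlog[v] + log(mx)
    }
  }
  list(out = out, outlog = outlog)
}

## index of the edge leading into node v (v must not be the root)
e_in <- function(tree, v) match(v, tree$edge[, 2])

## One full-likelihood evaluation helper used by the kappa/omega step.
## par_log = log(kappa), log(omega_1..k), log(scale_1..k): the scale
## factors multiply the branch lengths of each class, letting the bounded
## quasi-Newton step move along the omega/branch-length ridge that pure
## coordinate cycling zigzags on.
.full_lnL <- function(par_log, tree, lengths, classes, pi, pat, nclass,
                      tipmats = NULL) {
  k <- length(nclass)
  kappa <- exp(par_log[1])
  omegas <- exp(par_log[2:(k + 1)])
  scales <- exp(par_log[(k + 2):(2 * k + 1)])
  eigens <- lapply(seq_along(nclass), function(i) {
    codon_eigen(build_rate_matrix(kappa, omegas[i], pi))
  })
  names(eigens) <- names(nclass)
  lens <- lengths * scales[match(classes, names(nclass))]
  .prune(tree, lens, classes, eigens, pi, pat, tipmats = tipmats)$lnL
}

#' Fit a codon substitution model by maximum likelihood
#'
#' Fits either the one-ratio model \code{M0} (a single \eqn{\omega} shared
#' by every branch) or the branch model \code{Mb} (one \eqn{\omega} per
#' branch class, classes taken from \code{attr(tree, "edge_class")}) to a
#' codon alignment on a fixed rooted topology.  Branch lengths,
#' \eqn{\kappa} and the \eqn{\omega}'s are free parameters; codon
#' frequencies are fixed at their F3x4 estimates (or uniform).  The fit is
#' repeated from every initial \eqn{\omega} in \code{starts} and the best
#' replicate is returned; convergence additionally requires that at least
#' two starts agree within \code{1e-3} log-likelihood units.
#'
#' @param alignment named character vector of in-frame codon sequences.
#' @param tree rooted binary \code{phylo}; topology is fixed, branch
#'   lengths are used only as initial values (default 0.1 when absent).
#' @param model \code{"M0"} or \code{"Mb"}.
#' @param starts numeric vector of initial omega values (default
#'   \code{c(0.5, 1, 2)}).
#' @param freq \code{"f3x4"} (default) or \code{"uniform"} codon
#'   frequencies.
#' @param tol convergence tolerance on the cycle-to-cycle log-likelihood
#'   improvement (default \code{1e-6}).
#' @param max_cycles maximum number of coordinate cycles per start
#'   (default 200).
#' @param kappa_init initial transition/transversion ratio (default 2).
#' @param quiet suppress per-start progress messages.
#' @return object of class \code{branch_model_fit}: a list with elements
#'   \code{model}, \code{lnL}, \code{np}, \code{params} (kappa,
#'   omega_by_class, pi), \code{tree} (with fitted branch lengths),
#'   \code{converged}, \code{n_starts_agreeing} and \code{start_lnL}.
#' @export
fit_model <- function(alignment, tree, model = c("M0", "Mb"),
                      starts = c(0.5, 1, 2), freq = c("f3x4", "uniform"),
                      tol = 1e-6, max_cycles = 200, kappa_init = 2,
                      quiet = TRUE) {
  model <- match.arg(model)
  freq <- match.arg(freq)
  check_classed_tree(tree)
  classes <- if (model == "M0") rep("all", nrow(tree$edge)) else
    edge_classes(tree)
  class_names <- sort(unique(classes))
  pi <- if (freq == "f3x4") estimate_f3x4(alignment) else
    stats::setNames(rep(1 / 61, 61), CODONS61)
  np_freq <- if (freq == "f3x4") 9L else 0L
  pat <- codon_patterns(alignment[tree$tip.label])
  tipmats <- .tip_partials(tree, pat)
  pi_u <- unname(pi)

  init_len <- tree$edge.length
  if (is.null(init_len)) init_len <- rep(0.1, nrow(tree$edge))
  init_len <- pmin(pmax(init_len, 0.05), 5)

  runs <- lapply(starts, function(w0) {
    .fit_one_start(tree, pat, tipmats, classes, class_names, pi_u, init_len,
                   kappa0 = kappa_init, omega0 = rep(w0, length(class_names)),
                   tol = tol, max_cycles = max_cycles, quiet = quiet)
  })
  lnls <- vapply(runs, `[[`, numeric(1), "lnL")
  best <- which.max(lnls)
  fit <- runs[[best]]
  n_agree <- sum(lnls >= fit$lnL - 1e-3)
  tree_out <- tree
  tree_out$edge.length <- fit$lengths
  omega_by_class <- stats::setNames(fit$omega, class_names)
  structure(list(
    model = model,
    lnL = fit$lnL,
    np = nrow(tree$edge) + 1L + length(class_names) + np_freq,
    params = list(kappa = fit$kappa, omega_by_class = omega_by_class,
                  pi = pi),
    tree = tree_out,
    converged = fit$converged && (length(starts) < 2 || n_agree >= 2),
    n_starts_agreeing = n_agree,
    start_lnL = stats::setNames(lnls, paste0("omega0=", starts)),
    freq_model = freq
  ), class = "branch_model_fit")
}

## single optimisation run from one set of initial values
.fit_one_start <- function(tree, pat, tipmats, classes, class_names, pi,
                           lengths, kappa0, omega0, tol, max_cycles, quiet) {
  kappa <- kappa0
  omega <- omega0
  nclassv <- seq_along(class_names)
  names(nclassv) <- class_names
  lnL <- -Inf
  converged <- FALSE
  bb <- .FIT_BOUNDS
  for (cycle in seq_len(max_cycles)) {
    eigens <- lapply(omega, function(w) {
      codon_eigen(build_rate_matrix(kappa, w, pi))
    })
    names(eigens) <- class_names
    ## ---- branch sweep with periodically refreshed partials ----
    sweep <- .branch_sweep(tree, lengths, classes, eigens, pi, pat, tipmats)
    cand_len <- sweep$lengths
    pr <- .prune(tree, cand_len, classes, eigens, pi, pat,
                 tipmats = tipmats)
    if (pr$lnL + 1e-9 >= lnL) {
      lengths <- cand_len
      lnL_branch <- pr$lnL
    } else {
      lnL_branch <- lnL  # reject a (rare) non-improving stale sweep
    }
    ## ---- joint kappa / omega / class-scale refinement ----
    k <- length(omega)
    par0 <- log(c(kappa, omega, rep(1, k)))
    opt <- stats::optim(
      par0, .full_lnL, method = "L-BFGS-B",
      lower = log(c(bb$kappa[1], rep(bb$omega[1], k), rep(0.02, k))),
      upper = log(c(bb$kappa[2], rep(bb$omega[2], k), rep(50, k))),
      control = list(fnscale = -1, maxit = 40, factr = 1e8),
      tree = tree, lengths = lengths, classes = classes, pi = pi,
      pat = pat, nclass = nclassv, tipmats = tipmats)
    if (opt$value + 1e-9 >= lnL_branch) {
      kappa <- exp(opt$par[1])
      omega <- exp(opt$par[2:(k + 1)])
      scales <- exp(opt$par[(k + 2):(2 * k + 1)])
      lengths <- pmin(pmax(lengths * scales[match(classes, class_names)],
                           bb$blen[1]), bb$blen[2])
      new_lnL <- opt$value
    } else {
      new_lnL <- lnL_branch
    }
    if (!quiet) {
      message(sprintf("cycle %d lnL %.6f", cycle, new_lnL))
    }
    if (is.finite(lnL) && new_lnL - lnL < tol) {
      lnL <- max(new_lnL, lnL)
      converged <- TRUE
      break
    }
    lnL <- max(new_lnL, lnL)
  }
  list(lnL = lnL, kappa = kappa, omega = omega, lengths = lengths,
       converged = converged)
}

## One pass over all edges optimising each length by Brent, using inside
## ("down") and outside partials; partials are refreshed every few edges to
## bound staleness.
.branch_sweep <- function(tree, lengths, classes, eigens, pi, pat,
                          tipmats = NULL, refresh_every = 7L) {
  nt <- length(tree$tip.label)
  edge <- tree$edge
  wts <- pat$weights
  bb <- .FIT_BOUNDS$blen
  edges <- seq_len(nrow(edge))
  since_refresh <- Inf
  pr <- NULL; os <- NULL
  for (e in edges) {
    if (since_refresh >= refresh_every) {
      pr <- .prune(tree, lengths, classes, eigens, pi, pat,
                   keep_partials = TRUE, tipmats = tipmats)
      os <- .outside(tree, pr, pi)
      since_refresh <- 0L
    }
    v <- edge[e, 2]
    cm <- if (v <= nt) pr$tipmats[[v]] else pr$down[[v]]
    ov <- os$out[[v]]
    eg <- eigens[[classes[e]]]
    f <- function(t) {
      P <- p_matrix(eg, t)
      site <- colSums(ov * (P %*% cm))
      sum(wts * log(site))
    }
    opt <- stats::optimize(f, interval = c(bb[1], min(bb[2], 10)),
                           maximum = TRUE, tol = 1e-4)
    ## optimize() can miss a boundary optimum; check the lower bound
    if (f(bb[1]) > opt$objective) {
      lengths[e] <- bb[1]
    } else {
      lengths[e] <- opt$maximum
    }
    since_refresh <- since_refresh + 1L
  }
  list(lengths = lengths)
}

#' Likelihood-ratio test between two nested codon model fits
#'
#' @param fit_null,fit_alt objects from [fit_model()] fitted to the same
#'   alignment and topology, with \code{fit_null$np < fit_alt$np}.
#' @return object of class \code{lrt_result}: list with \code{stat}
#'   (\eqn{2\Delta lnL}, clamped to zero when negative within numerical
#'   tolerance), \code{df} (\eqn{\Delta np}) and \code{p} (chi-square upper
#'   tail).
#' @export
lrt <- function(fit_null, fit_alt) {
  if (fit_alt$np <= fit_null$np) {
    stop("alternative model must have more parameters than the null (np ",
         fit_alt$np, " <= ", fit_null$np, ")")
  }
  stat <- 2 * (fit_alt$lnL - fit_null$lnL)
  if (stat < 0) {
    if (stat < -0.1) {
      warning("alternative fit has distinctly lower likelihood than the ",
              "null (2dlnL = ", format(stat), "); check convergence")
    }
    stat <- 0
  }
  df <- as.integer(fit_alt$np - fit_null$np)
  structure(list(stat = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.branch_model_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, np = %d, kappa = %.4f%s\n",
              x$model, x$lnL, x$np, x$params$kappa,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  om <- x$params$omega_by_class
  cat("omega by class:\n")
  for (nm in names(om)) cat(sprintf("  %-12s %.4f\n", nm, om[[nm]]))
  cat(sprintf("starts agreeing within 1e-3 lnL: %d of %d\n",
              x$n_starts_agreeing, length(x$start_lnL)))
  invisible(x)
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: 2dlnL = %.4f, df = %d, p = %.3g\n", x$stat, x$df, x$p))
  invisible(x)
}
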