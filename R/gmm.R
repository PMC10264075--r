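#' Univariate Gaussian mixture model with BIC model selection
#'
#' Fits univariate Gaussian mixtures by EM for every component count
#' `G = 1..G_max` under both an equal-variance and a free-variance model,
#' and selects the fit maximizing `BIC = 2*loglik - k*log(n)` (the
#' maximized-BIC convention; users of the minimized convention can negate
#' the table).  Initialization is deterministic: a quantile-based hard
#' partition plus `n_restarts` internally seeded random partitions, keeping
#' the best final log-likelihood; ties in BIC are broken toward smaller G,
#' then toward the equal-variance model.  Component variances are floored at
#' a small fraction of the data variance for numerical stability; fits whose
#' variances collapse to the floor (below `1e-12` of the data variance) or
#' whose mixing proportions vanish are flagged degenerate and excluded from
#' selection.
#'
#' @param values numeric vector of per-specimen scalars (n >= 5, finite).
#' @param G_max largest number of components tried (default 9).
#' @param n_restarts random restarts per (model, G) in addition to the
#'   quantile initialization (default 10).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return object of class `gmm_result`: `selected_G`, `selected_model`
#'   (`"equal_variance"` or `"variable_variance"`), `bic_table` (2 x G_max,
#'   NA where a fit was degenerate or unavailable), `means`, `variances`,
#'   `mixing_proportions`, `assignments`, `posterior`, `loglik`,
#'   `loglik_trace` (non-decreasing), `fits` (all per-(model, G) fits).
#' @export
fit_gmm_1d <- function(values, G_max = 9L, n_restarts = 10L,
                       max_iter = 200L, tol = 1e-6) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("values must be finite")
  n <- length(x)
  if (n < 5L) stop("mixture fitting needs at least 5 values")
  vx <- stats::var(x)
  if (vx == 0) {
    warning("all values identical: returning a single zero-variance component")
    post <- matrix(1, n, 1)
    return(structure(list(selected_G = 1L, selected_model = "equal_variance",
                          bic_table = matrix(NA_real_, 2, G_max,
                                             dimnames = list(c("equal_variance",
                                                               "variable_variance"),
                                                             paste0("G", 1:G_max))),
                          means = x[1], variances = 0,
                          mixing_proportions = 1,
                          assignments = rep(1L, n), posterior = post,
                          loglik = Inf, loglik_trace = Inf,
                          fits = list()),
                     class = "gmm_result"))
  }
  G_max <- as.integer(G_max)
  models <- c("equal_variance", "variable_variance")
  bic <- matrix(NA_real_, 2, G_max,
                dimnames = list(models, paste0("G", 1:G_max)))
  fits <- list()
  for (m in models) for (G in 1:G_max) {
    fit <- best_em_fit(x, G, equal = (m == "equal_variance"),
                       n_restarts = n_restarts, max_iter = max_iter,
                       tol = tol)
    if (is.null(fit)) next
    k <- if (m == "equal_variance") 2L * G else 3L * G - 1L
    fit$bic <- 2 * fit$loglik - k * log(n)
    fit$model <- m; fit$G <- G
    fits[[paste(m, G, sep = ".")]] <- fit
    if (!fit$degenerate) bic[m, paste0("G", G)] <- fit$bic
  }
  if (all(is.na(bic))) stop("no non-degenerate mixture fit found")
  ## best BIC; ties -> smaller G, then equal variance (row order does this)
  best <- which(bic == max(bic, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(best[, "col"], best[, "row"]), , drop = FALSE][1, ]
  sel <- fits[[paste(models[best["row"]], best["col"], sep = ".")]]
  structure(list(selected_G = sel$G, selected_model = sel$model,
                 bic_table = bic,
                 means = sel$mean, variances = sel$var,
                 mixing_proportions = sel$pi,
                 assignments = sel$assignments, posterior = sel$posterior,
                 loglik = sel$loglik, loglik_trace = sel$trace,
                 fits = fits),
            class = "gmm_result")
}

#' @export
print.gmm_result <- function(x, ...) {
  cat(sprintf("<gmm_result> selected G = %d (%s), BIC = %.2f\n",
              x$selected_G, x$selected_model,
              max(x$bic_table, na.rm = TRUE)))
  if (x$selected_G > 1)
    cat("  proportions:", paste(sprintf("%.2f", x$mixing_proportions),
                                collapse = " "), "\n")
  invisible(x)
}

## Run EM from the quantile init and n_restarts seeded random inits.
## Restarts are short runs (capped iterations); only the best short run is
## polished to full convergence — the usual short-run EM initialization
## strategy.  RNG state of the caller is untouched.
best_em_fit <- function(x, G, equal, n_restarts, max_iter, tol) {
  n <- length(x)
  inits <- list(quantile_partition(x, G))
  if (G > 1 && n_restarts > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()), add = TRUE)
    for (r in seq_len(n_restarts)) {
      set.seed(1000L + 97L * G + 7L * r + as.integer(equal))
      inits[[length(inits) + 1L]] <- sample.int(G, n, replace = TRUE)
    }
  }
  best <- NULL
  for (z in inits) {
    if (length(unique(z)) < G) next
    fit <- em_1d(x, G, z, equal = equal,
                 max_iter = min(25L, max_iter), tol = tol)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik + 1e-12) {
      best <- fit; best$init <- z
    }
  }
  if (is.null(best)) return(NULL)
  fit <- em_1d(x, G, best$init, equal = equal, max_iter = max_iter,
               tol = tol)
  fit
}

quantile_partition <- function(x, G) {
  br <- stats::quantile(x, probs = seq(0, 1, length.out = G + 1L))
  br[1] <- -Inf; br[G + 1L] <- Inf
  br <- unique(br)
  z <- as.integer(cut(x, breaks = br, include.lowest = TRUE))
  if (length(unique(z)) < G) z <- as.integer(cut(rank(x, ties.method = "first"),
                                                 breaks = G))
  z
}

## EM for a univariate Gaussian mixture from a hard initial partition.
em_1d <- function(x, G, z0, equal, max_iter, tol) {
  n <- length(x); vx <- stats::var(x)
  floor_var <- 1e-12 * vx
  pi_g <- tabulate(z0, G) / n
  mu <- vapply(seq_len(G), function(g) mean(x[z0 == g]), numeric(1))
  if (equal) {
    s2 <- rep(max(sum((x - mu[z0])^2) / n, floor_var), G)
  } else {
    s2 <- vapply(seq_len(G), function(g)
      max(stats::var(x[z0 == g]) * (sum(z0 == g) - 1) / max(sum(z0 == g), 1),
          floor_var, na.rm = TRUE), numeric(1))
  }
  s2[!is.finite(s2)] <- vx
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dev <- outer(x, mu, `-`)^2
    logd <- -0.5 * dev * rep(1 / s2, each = n) +
      rep(log(pi_g) - 0.5 * log(2 * pi * s2), each = n)
    mx <- logd[cbind(seq_len(n), max.col(logd, ties.method = "first"))]
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    post <- exp(logd - lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        ll - ll_old < tol * (1 + abs(ll)) && ll - ll_old > -1e-6) break
    ll_old <- ll
    nk <- colSums(post)
    if (any(nk < 1e-10)) return(em_pack(x, G, mu, s2, pi_g, post, ll, trace,
                                        floor_var, nk, degenerate = TRUE))
    pi_g <- nk / n
    mu <- colSums(post * x) / nk
    dev <- outer(x, mu, `-`)^2
    if (equal) {
      s2 <- rep(max(sum(post * dev) / n, floor_var), G)
    } else {
      s2 <- pmax(colSums(post * dev) / nk, floor_var)
    }
  }
  em_pack(x, G, mu, s2, pi_g, post, ll, trace, floor_var,
          colSums(post), degenerate = FALSE)
}

## A fit is degenerate (excluded from BIC selection, but still reported)
## when any component variance collapses to the rejection floor (1e-12 of
## the data variance) or any component's effective membership drops below 2
## points — a Gaussian variance is meaningless on fewer.
em_pack <- function(x, G, mu, s2, pi_g, post, ll, trace, floor_var, nk,
                    degenerate) {
  ord <- order(mu)
  mu <- mu[ord]; s2 <- s2[ord]; pi_g <- pi_g[ord]
  post <- post[, ord, drop = FALSE]
  degenerate <- degenerate ||
    any(s2 <= floor_var * (1 + 1e-6)) ||
    any(nk < 2 - 1e-9)
  list(mean = mu, var = s2, pi = pi_g, posterior = post,
       assignments = max.col(post, ties.method = "first"),
       loglik = ll, trace = trace,
       degenerate = degenerate || any(pi_g < 1e-6))
}
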