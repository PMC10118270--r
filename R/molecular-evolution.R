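#' Pairwise Ka/Ks by Nei-Gojobori counting with Jukes-Cantor correction
#'
#' Synonymous site fractions per codon are derived from the nine
#' single-mutation neighbours under the standard genetic code and averaged
#' across the two sequences; synonymous/nonsynonymous differences are
#' counted by equal-weight averaging over all minimal mutational pathways
#' between differing codons (pathways through stop codons excluded, with a
#' fall-back to all pathways when every one is blocked). The Jukes-Cantor
#' correction `d = -3/4 log(1 - 4/3 p)` is applied separately to
#' `pS = Sd/S` and `pN = Nd/N`.
#'
#' Sequences must be pre-aligned (equal length, no gaps); codons containing
#' ambiguity characters, gap characters or stop codons in either sequence
#' are skipped.
#'
#' @param cds_a,cds_b in-frame coding sequences of equal length.
#' @return a one-row data.frame: `S`, `N` (site counts, `S + N` = 3 x
#'   aligned codons), `Sd`, `Nd` (pathway-averaged differences), `pS`, `pN`,
#'   `Ks`, `Ka`, `omega` (= Ka/Ks, `NA` when Ks is 0), `n_codons`,
#'   `saturated` (p >= 3/4 on either class; Ks/Ka then `NA`).
#' @export
estimate_ka_ks <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b))
    stop("sequences differ in length (", nchar(cds_a), " vs ", nchar(cds_b), ")",
         call. = FALSE)
  tab <- codon_tables()
  ia <- cds_to_codons(cds_a)
  ib <- cds_to_codons(cds_b)
  ok <- !is.na(ia) & !is.na(ib) & !tab$is_stop[ia] & !tab$is_stop[ib]
  ia <- ia[ok]; ib <- ib[ok]
  n_codons <- length(ia)
  if (n_codons == 0) stop("no usable codons", call. = FALSE)
  S <- (sum(tab$syn_sites[ia]) + sum(tab$syn_sites[ib])) / 2
  N <- 3 * n_codons - S
  Sd <- sum(tab$sd[cbind(ia, ib)])
  Nd <- sum(tab$nd[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  saturated <- pS >= 0.75 || pN >= 0.75
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  Ks <- if (saturated) NA_real_ else jc(pS)
  Ka <- if (saturated) NA_real_ else jc(pN)
  omega <- if (!saturated && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
             Ks = Ks, Ka = Ka, omega = omega,
             n_codons = n_codons, saturated = saturated)
}

#' Ka/Ks for a table of gene pairs
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` (extra columns are
#'   carried through).
#' @param cds named character vector of coding sequences.
#' @return `pairs` with the [estimate_ka_ks()] columns appended; pairs whose
#'   sequences are missing or of unequal length get `NA` statistics.
#' @export
kaks_table <- function(pairs, cds) {
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- cds[[pairs$gene_a[i]]]
    b <- cds[[pairs$gene_b[i]]]
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b) || nchar(a) != nchar(b))
      return(data.frame(S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
                        pS = NA_real_, pN = NA_real_, Ks = NA_real_, Ka = NA_real_,
                        omega = NA_real_, n_codons = NA_integer_, saturated = NA))
    estimate_ka_ks(a, b)
  })
  cbind(pairs, do.call(rbind, res))
}

#' Fit a Gaussian mixture to a Ks distribution
#'
#' Expectation-maximization fits of 1..`max_components` univariate Gaussian
#' mixtures to the Ks values (filtered to `0 < Ks <= ks_max`, the saturation
#' cutoff), each from `n_restarts` k-means-seeded restarts; the component
#' count is chosen by minimum BIC. Per-iteration log-likelihoods are checked
#' to be non-decreasing, a structural property of EM.
#'
#' @param ks_values numeric vector of Ks values.
#' @param ks_max saturation cutoff (default 4.0).
#' @param max_components largest mixture size tried.
#' @param n_restarts k-means-seeded EM restarts per component count.
#' @param max_iter EM iteration cap; non-convergence flags the fit.
#' @param tol log-likelihood convergence tolerance.
#' @param log_space fit on log(Ks) instead of raw Ks (off by default; peak
#'   means are reported back on the raw scale either way).
#' @return object of class `ks_mixture_fit`: list with `components` (weight,
#'   mean, sd, sorted by mean), `k` (chosen count), `bic` (per candidate
#'   count), `loglik`, `converged`, `n`, `ks_max`.
#' @export
fit_ks_mixture <- function(ks_values, ks_max = 4.0, max_components = 4L,
                           n_restarts = 10L, max_iter = 500L, tol = 1e-8,
                           log_space = FALSE) {
  x <- ks_values[is.finite(ks_values) & ks_values > 0 & ks_values <= ks_max]
  if (length(x) < 50)
    stop("only ", length(x), " usable Ks values (need >= 50); provide more pairs",
         call. = FALSE)
  if (log_space) x <- log(x)
  fits <- vector("list", max_components)
  bic <- rep(NA_real_, max_components)
  for (k in seq_len(max_components)) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      f <- em_gaussian_mixture(x, k, max_iter = max_iter, tol = tol)
      if (is.null(best) || f$loglik > best$loglik) best <- f
      if (k == 1) break  # closed form, restarts identical
    }
    fits[[k]] <- best
    n_par <- 3 * k - 1
    bic[k] <- -2 * best$loglik + n_par * log(length(x))
  }
  k_best <- which.min(bic)
  fit <- fits[[k_best]]
  comp <- data.frame(weight = fit$weight, mean = fit$mean, sd = fit$sd)
  if (log_space) comp$mean <- exp(comp$mean + comp$sd^2 / 2)  # back-transform
  comp <- comp[order(comp$mean), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(components = comp, k = k_best, bic = bic,
                 loglik = fit$loglik, converged = fit$converged,
                 n = length(x), ks_max = ks_max, log_space = log_space),
            class = "ks_mixture_fit")
}

#' @export
print.ks_mixture_fit <- function(x, ...) {
  cat("<ks_mixture_fit>", x$k, "component(s) over", x$n, "values",
      if (!x$converged) "(EM not converged)" else "", "\n")
  print(x$components, row.names = FALSE)
  invisible(x)
}

# univariate Gaussian-mixture EM with k-means initialisation; asserts the
# log-likelihood never decreases between iterations
em_gaussian_mixture <- function(x, k, max_iter = 500L, tol = 1e-8) {
  n <- length(x)
  if (k == 1) {
    mu <- mean(x); sdv <- stats::sd(x) * sqrt((n - 1) / n)
    ll <- sum(stats::dnorm(x, mu, sdv, log = TRUE))
    return(list(weight = 1, mean = mu, sd = sdv, loglik = ll, converged = TRUE))
  }
  km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 1))
  mu <- as.vector(km$centers)
  sdv <- vapply(seq_len(k), function(j) {
    s <- stats::sd(x[km$cluster == j])
    if (is.na(s) || s < 1e-4) 1e-4 else s
  }, numeric(1))
  w <- as.vector(table(factor(km$cluster, levels = seq_len(k)))) / n
  w[w == 0] <- 1e-6; w <- w / sum(w)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sdv[j]), numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d < 1e-300] <- 1e-300
    ll <- sum(log(rowsum_d))
    if (ll < ll_old - 1e-6)
      stop("EM log-likelihood decreased (", ll_old, " -> ", ll, ")", call. = FALSE)
    done <- it > 1 && ll - ll_old < tol
    ll_old <- ll
    if (done) {
      converged <- TRUE
      break
    }
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sdv <- sqrt(colSums(resp * (outer(x, mu, "-")^2)) / nk)
    sdv[sdv < 1e-4] <- 1e-4
  }
  list(weight = w, mean = mu, sd = sdv, loglik = ll_old, converged = converged)
}

#' Label mixture components with polyploidy events
#'
#' Components, sorted by increasing mean Ks, receive the event labels in the
#' order given (young to old); surplus components are labelled
#' `"unassigned"`, surplus labels are dropped with a warning.
#'
#' @param fit a `ks_mixture_fit`.
#' @param event_labels event names ordered young to old.
#' @return the fit with a `label` column added to `components`.
#' @export
assign_ks_peaks <- function(fit, event_labels) {
  k <- nrow(fit$components)
  if (length(event_labels) > k) {
    warning("more event labels (", length(event_labels), ") than components (",
            k, "); older label(s) dropped: ",
            paste(event_labels[(k + 1):length(event_labels)], collapse = ", "),
            call. = FALSE)
    event_labels <- event_labels[seq_len(k)]
  }
  lab <- rep("unassigned", k)
  lab[seq_along(event_labels)] <- event_labels
  fit$components$label <- lab
  fit
}
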