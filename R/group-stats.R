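#' Two-sided two-sample Kolmogorov-Smirnov comparison
#'
#' `D = sup |ECDF_a - ECDF_b|` is computed exactly by evaluating both
#' right-continuous ECDFs at every pooled data value (the sup of either
#' one-sided difference is attained there, also under ties). The p-value
#' uses the asymptotic Kolmogorov distribution at
#' `lambda = sqrt(n*m / (n+m)) * D` (effective-n correction), appropriate
#' for the group sizes of typical per-condition axon cohorts (n >= ~20).
#'
#' @param a,b numeric samples, each with at least 2 values.
#' @param label_a,label_b names carried into the result.
#' @return object of class `ks_comparison`: list with `label_a`,
#'   `label_b`, `D`, `p`, `n_a`, `n_b`.
#' @examples
#' ks2(rnorm(30), rnorm(30, 1))
#' @export
ks2 <- function(a, b, label_a = "a", label_b = "b") {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA",
                                 call. = FALSE)
  pooled <- sort(unique(c(a, b)))
  sa <- sort(a); sb <- sort(b)
  Fa <- findInterval(pooled, sa) / length(a)
  Fb <- findInterval(pooled, sb) / length(b)
  D <- max(abs(Fa - Fb))
  ne <- length(a) * length(b) / (length(a) + length(b))
  p <- kolmogorov_sf(sqrt(ne) * D)
  structure(list(label_a = label_a, label_b = label_b, D = D, p = p,
                 n_a = length(a), n_b = length(b)),
            class = "ks_comparison")
}

# asymptotic Kolmogorov survival function Q(lambda)
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:101
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, .Machine$double.xmin), 1)
}

#' @export
print.ks_comparison <- function(x, ...) {
  cat(sprintf("KS %s vs %s: D = %.4f, p = %.3g (n = %d, %d)\n",
              x$label_a, x$label_b, x$D, x$p, x$n_a, x$n_b))
  invisible(x)
}

# figure-legend star convention
p_stars <- function(p) {
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "n.s.")))
}

#' Summarize amplitude groups and compare conditions
#'
#' Per group: mean, SEM (`sd / sqrt(n)` with the n-1 sample standard
#' deviation), and n -- the "mean +/- SEM, axon number per condition"
#' reporting convention. Pairwise contrasts are compared with the
#' two-sided KS test ([ks2()]) and annotated with significance stars
#' (p <= 0.05 `*`, <= 0.01 `**`, <= 0.001 `***`). Raw p-values are
#' reported per contrast without multiplicity correction.
#'
#' @param groups named list of numeric vectors (one per condition, names
#'   are labels).
#' @param contrasts list of `c(label_a, label_b)` pairs, or `"all"`
#'   (default) for every unordered pair in label order.
#' @return object of class `group_summary`: list with `summary`
#'   (data.frame label/n/mean/sem) and `comparisons` (data.frame
#'   label_a/label_b/D/p/stars; zero rows when fewer than two groups).
#' @examples
#' summarize_groups(list(NGF = c(0.8, 0.9, 0.7), TD = c(0.2, 0.3, 0.25)))
#' @export
summarize_groups <- function(groups, contrasts = "all") {
  stopifnot(is.list(groups), length(groups) >= 1,
            !is.null(names(groups)), all(nzchar(names(groups))))
  if (anyDuplicated(names(groups)))
    stop("group labels must be unique", call. = FALSE)
  for (g in groups)
    if (length(g) < 1) stop("each group must be nonempty", call. = FALSE)
  labs <- names(groups)
  summary <- data.frame(
    label = labs,
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sem = vapply(groups, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (identical(contrasts, "all")) {
    contrasts <- list()
    if (length(labs) >= 2)
      for (i in seq_len(length(labs) - 1))
        for (j in (i + 1):length(labs))
          contrasts[[length(contrasts) + 1]] <- c(labs[i], labs[j])
  }
  comp <- data.frame(label_a = character(0), label_b = character(0),
                     D = numeric(0), p = numeric(0), stars = character(0),
                     stringsAsFactors = FALSE)
  for (ct in contrasts) {
    stopifnot(length(ct) == 2, all(ct %in% labs))
    k <- ks2(groups[[ct[1]]], groups[[ct[2]]], ct[1], ct[2])
    comp <- rbind(comp, data.frame(label_a = ct[1], label_b = ct[2],
                                   D = k$D, p = k$p, stars = p_stars(k$p),
                                   stringsAsFactors = FALSE))
  }
  structure(list(summary = summary, comparisons = comp),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Group summary (mean +/- SEM):\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-10s %7.4f +/- %.4f  (n = %d)\n",
                x$summary$label[i], x$summary$mean[i], x$summary$sem[i],
                x$summary$n[i]))
  if (nrow(x$comparisons) > 0) {
    cat("Two-sided KS comparisons:\n")
    for (i in seq_len(nrow(x$comparisons)))
      cat(sprintf("  %s vs %s: D = %.3f, p = %.3g %s\n",
                  x$comparisons$label_a[i], x$comparisons$label_b[i],
                  x$comparisons$D[i], x$comparisons$p[i],
                  x$comparisons$stars[i]))
  }
  invisible(x)
}
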