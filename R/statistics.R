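#' Pearson correlation with two-sided significance
#'
#' Product-moment correlation with the t-test significance used for the
#' transect-wide proxy-environment screen: t = R sqrt((n-2)/(1-R^2)) on
#' n - 2 degrees of freedom, two-sided. Missing values are removed pairwise;
#' |R| = 1 returns p = 0.
#'
#' @param x,y Numeric series of equal length (>= 3 complete pairs).
#' @return List: `r`, `p`, `n`.
#' @export
#' @examples
#' tx_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
tx_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1 - 1e-15) 0 else ct$p.value
  list(r = r, p = p, n = n)
}

#' Correlation screen between proxy profiles and environmental fields
#'
#' Evaluates every proxy-environment column pair shared across samples with
#' [tx_pearson()] and flags pairs at the significance threshold. No
#' multiple-testing correction is applied by default (flat alpha screen);
#' Benjamini-Hochberg adjusted flags can be added as a clearly separated
#' extension column.
#'
#' @param proxies Tibble with `sample_id` plus numeric proxy columns.
#' @param env Tibble with `sample_id` plus numeric environmental columns.
#' @param alpha Significance threshold (default 0.05).
#' @param adjust Also report Benjamini-Hochberg adjusted flags (default
#'   FALSE).
#' @return Long tibble: `proxy`, `env`, `n`, `r`, `p`, `significant`, and
#'   `significant_bh` when `adjust = TRUE`.
#' @export
correlation_matrix <- function(proxies, env, alpha = 0.05, adjust = FALSE) {
  stopifnot("sample_id" %in% names(proxies), "sample_id" %in% names(env))
  merged <- dplyr::inner_join(proxies, env, by = "sample_id",
                              suffix = c("", ".env"))
  if (nrow(merged) == 0) stop("no shared samples", call. = FALSE)
  pnames <- setdiff(names(proxies), "sample_id")
  enames <- setdiff(names(env), "sample_id")
  enames_m <- ifelse(enames %in% pnames, paste0(enames, ".env"), enames)
  rows <- list()
  for (i in seq_along(pnames)) {
    for (j in seq_along(enames)) {
      x <- merged[[pnames[i]]]
      y <- merged[[enames_m[j]]]
      res <- tryCatch(tx_pearson(x, y), error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        proxy = pnames[i], env = enames[j],
        n = res$n, r = res$r, p = res$p
      )
    }
  }
  if (length(rows) == 0) stop("no evaluable proxy-environment pairs", call. = FALSE)
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(significant = .data$p <= alpha)
  if (adjust) {
    out$significant_bh <- stats::p.adjust(out$p, method = "BH") <= alpha
  }
  out
}
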