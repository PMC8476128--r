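#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return Named numeric vector with `estimate`, `lower`, `upper`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated format used for gene-set collections: one set per
#' line, `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path file path.
#' @return Named list of character vectors (set members), with the
#'   description stored in the `"description"` attribute of each element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed GMT line: ", substr(ln, 1, 60))
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    attr(members, "description") <- parts[2]
    sets[[parts[1]]] <- members
  }
  sets
}

#' Write gene-sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Least-squares fit with coefficient table; design must be full rank.
# Returns list(coef, se, t, df, sigma2, XtXinv). Errors name collinear
# columns so callers can surface a useful degenerate-design message.
ols_fit <- function(X, y) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qrx, y)
  res <- y - X %*% coef
  df <- nrow(X) - ncol(X)
  if (df <= 0) stop("not enough observations for the design")
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(X)
  list(coef = drop(coef), se = se, t = drop(coef) / se, df = df,
       sigma2 = sigma2, XtXinv = XtXinv)
}
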