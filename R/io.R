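#' Write a distribution, moments or scan table as TSV with a comment header
#'
#' All on-disk outputs share one format: a block of `#`-prefixed header
#' lines recording the parameter set, software version and any extra
#' metadata, followed by a tab-separated table. Distributions have columns
#' `(n, probability)`; promoter-resolved distributions `(n, P0, P1)`;
#' moments a single row; scan tables their own columns.
#'
#' @param pmf a [discrete_pmf()].
#' @param path output file path.
#' @param params optional [gene_params()] recorded in the header.
#' @param extra named character vector of extra header fields.
#' @return The path, invisibly.
#' @export
write_pmf_tsv <- function(pmf, path, params = NULL, extra = NULL) {
  stopifnot(inherits(pmf, "discrete_pmf"))
  df <- data.frame(n = 0:support_max(pmf), probability = as.numeric(pmf))
  extra <- c(extra, truncation = as.character(support_max(pmf)),
             residual = format(attr(pmf, "residual")))
  write_tsv_with_header(df, path, params, extra)
}

#' @rdname write_pmf_tsv
#' @param x a `promoter_pmf` from [cme_steady_state()].
#' @export
write_promoter_pmf_tsv <- function(x, path, params = NULL, extra = NULL) {
  stopifnot(inherits(x, "promoter_pmf"))
  df <- data.frame(n = 0:x$n_max, P0 = x$p0, P1 = x$p1)
  write_tsv_with_header(df, path, params, extra)
}

#' @rdname write_pmf_tsv
#' @param mom a `moment_summary`.
#' @export
write_moments_tsv <- function(mom, path, params = NULL, extra = NULL) {
  stopifnot(inherits(mom, "moment_summary"))
  df <- data.frame(mean = mom$mean, variance = mom$variance,
                   noise = mom$noise)
  write_tsv_with_header(df, path, params, extra)
}

#' @rdname write_pmf_tsv
#' @param df a data frame (e.g. a scan table).
#' @export
write_scan_tsv <- function(df, path, params = NULL, extra = NULL) {
  write_tsv_with_header(df, path, params, extra)
}

write_tsv_with_header <- function(df, path, params = NULL, extra = NULL) {
  if (inherits(path, "connection")) {
    con <- path
  } else {
    con <- file(path, "w")
    on.exit(close(con))
  }
  writeLines(sprintf("# promleak %s",
                     as.character(utils::packageVersion("promleak"))), con)
  if (!is.null(params)) {
    writeLines(sprintf("# params: gamma1=%g gamma0=%g f=%g lambda1=%g lambda0=%g d=%g",
                       params$gamma1, params$gamma0, params$f,
                       params$lambda1, params$lambda0, params$d), con)
  }
  for (k in names(extra)) {
    writeLines(sprintf("# %s: %s", k, extra[[k]]), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV written by the package
#'
#' @param path file path.
#' @return A data frame; header comment lines are kept in attribute
#'   `"header"`.
#' @export
read_tsv_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  attr(df, "header") <- hdr
  df
}
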