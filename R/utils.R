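`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero to a fixed number of decimals
#'
#' Reporting helper matching the conventional rounding of printed tables
#' (base \code{round} rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## md5 of the deparsed object, used for config hashing in run metadata
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x, control = "all"), f)
  unname(tools::md5sum(f))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stop_ommtraj <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "ommtraj_error")))
}
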