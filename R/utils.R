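# Internal helpers shared across modules.

#' Natural-sort ordering of allele names
#'
#' Orders strings so that embedded integers compare numerically
#' ("IGHV3-9" before "IGHV3-20"), the convention used to pick
#' deterministic representatives and numbering throughout the package.
#'
#' @param x Character vector.
#' @return Integer permutation, as [order()].
#' @keywords internal
natural_order <- function(x) {
  x <- as.character(x)
  pieces <- strsplit(x, "(?<=\\D)(?=\\d)|(?<=\\d)(?=\\D)", perl = TRUE)
  n_tok <- max(lengths(pieces), 1L)
  keys <- vector("list", n_tok * 2L)
  for (i in seq_len(n_tok)) {
    tok <- vapply(pieces, function(p) if (length(p) >= i) p[[i]] else "", "")
    num <- suppressWarnings(as.numeric(tok))
    # numeric tokens sort before alphabetic ones of the same rank
    keys[[2L * i - 1L]] <- ifelse(is.na(num), Inf, num)
    keys[[2L * i]] <- ifelse(is.na(num), tok, "")
  }
  do.call(order, keys)
}

natural_sort <- function(x) x[natural_order(x)]

natural_min <- function(x) natural_sort(x)[1L]

#' Split a comma-separated allele call into distinct names
#' @keywords internal
split_call <- function(call) {
  out <- strsplit(as.character(call), "\\s*,\\s*")
  lapply(out, function(v) unique(v[nzchar(v)]))
}

#' IUIS gene name of an allele call (text before "*")
#' @keywords internal
iuis_gene <- function(allele) sub("\\*.*$", "", allele)

#' IUIS subgroup of an allele call (locus prefix plus leading digit run)
#' @keywords internal
iuis_subgroup <- function(allele) {
  r <- regexpr("^[A-Z]+[0-9]+", allele)
  ifelse(r > 0L,
         substr(allele, 1L, attr(r, "match.length")),
         iuis_gene(allele))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_ascgeno <- function(msg, class) {
  stop(structure(class = c(class, "ascgeno_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
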