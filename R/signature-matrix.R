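#' Construct a reference signature matrix
#'
#' A signature matrix holds one probability distribution over the 96
#' trinucleotide mutation channels per signature (columns). Rows are
#' canonicalized to the fixed channel order of [channel_labels()] regardless
#' of input order, so any row permutation of the same data yields the same
#' object. Columns whose sum is within `1e-3` of 1 are renormalized to sum
#' exactly 1; anything further off is rejected.
#'
#' @param weights numeric matrix, 96 rows (channels) by K columns
#'   (signatures), with rownames giving channel labels and colnames giving
#'   signature names.
#' @return matrix of class `signature_matrix` in canonical channel order,
#'   columns summing to 1.
#' @export
signature_matrix <- function(weights) {
  weights <- as.matrix(weights)
  if (nrow(weights) != 96L) {
    stop("signature matrix must have exactly 96 channel rows, got ",
         nrow(weights))
  }
  if (is.null(rownames(weights))) stop("signature matrix needs channel rownames")
  if (is.null(colnames(weights))) {
    colnames(weights) <- paste0("Sig", seq_len(ncol(weights)))
  }
  canon <- channel_labels()
  if (!setequal(rownames(weights), canon)) {
    stop("channel labels do not match the canonical 96-channel set; ",
         "unexpected: ",
         paste(head(setdiff(rownames(weights), canon)), collapse = ", "))
  }
  weights <- weights[canon, , drop = FALSE]
  if (any(weights < 0)) stop("signature weights must be non-negative")
  sums <- colSums(weights)
  off <- abs(sums - 1) > 1e-3
  if (any(off)) {
    stop("signature column(s) do not sum to 1 (tolerance 1e-3): ",
         paste(colnames(weights)[off], collapse = ", "))
  }
  weights <- sweep(weights, 2L, sums, "/")
  class(weights) <- c("signature_matrix", class(weights))
  weights
}

#' Read a signature matrix from TSV
#'
#' Expects a `context` column with the 96 channel labels plus one numeric
#' column per signature. Row order is irrelevant; the result is always in
#' canonical channel order.
#'
#' @param path file path.
#' @return a [signature_matrix()].
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"context" %in% names(df)) {
    stop("signature matrix file must have a 'context' column: ", path)
  }
  if (nrow(df) != 96L) {
    stop("signature matrix file must have 96 data rows, got ", nrow(df),
         ": ", path)
  }
  w <- as.matrix(df[setdiff(names(df), "context")])
  rownames(w) <- df$context
  signature_matrix(w)
}

#' Write a signature matrix to TSV
#'
#' @param x a [signature_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(x, path) {
  df <- data.frame(context = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
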