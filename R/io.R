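#' Read / write the package's plain-text interchange formats
#'
#' Cq plates travel as long-format CSV (plate_id, well_id, assay_id,
#' assay_role, well_role, time_point, cell_id, cq); matrices as TSV with
#' row names in the first column.
#'
#' @param cq a long-format Cq data.frame.
#' @param path file path.
#' @name coprofile-io
NULL

#' @rdname coprofile-io
#' @export
write_cq_csv <- function(cq, path) {
  utils::write.csv(as.data.frame(cq), path, row.names = FALSE, na = "")
}

#' @rdname coprofile-io
#' @export
read_cq_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$cq[out$cq == ""] <- NA
  out$cq <- as.numeric(out$cq)
  class(out) <- c("cq_plate", "data.frame")
  out
}

#' @rdname coprofile-io
#' @param x a numeric matrix.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' @rdname coprofile-io
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
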