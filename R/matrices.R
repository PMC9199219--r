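#' @title Typed expression matrices and delimited-text I/O
#' @description
#' All matrices in the package are plain numeric matrices with mandatory
#' dimnames: bulk matrices are genes x samples, cell-type expression (W)
#' matrices are genes x cell types, proportion (H) matrices are cell
#' types x samples with unit-sum columns, and signature matrices are W
#' matrices restricted to discriminating genes. `validate_matrix()`
#' enforces the invariants of each kind; `read_matrix()`/`write_matrix()`
#' move them to and from tab- or comma-delimited text.
#' @name matrix-io
NULL

MATRIX_KINDS <- c("bulk", "signature", "proportions", "cellexpr")

stop_domain <- function(msg, class = "scaddecon_domain_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Validate a typed matrix
#'
#' Checks the invariants attached to each matrix kind: numeric,
#' non-negative entries, unique row and column identifiers, at least one
#' row and column; additionally `proportions` columns must sum to 1
#' (within `1e-6`), `cellexpr` and `signature` need at least two cell
#' types, and `signature` needs at least as many genes as cell types.
#'
#' @param x numeric matrix with complete dimnames.
#' @param kind one of `"bulk"`, `"signature"`, `"proportions"`,
#'   `"cellexpr"`.
#' @return `x`, invisibly, possibly with proportions columns
#'   renormalized (see Details).
#' @details Proportions columns off unit sum by at most `1e-6` are
#'   silently renormalized; off by at most `0.05` they are renormalized
#'   with a warning; beyond that validation fails. This tolerates
#'   floating-point round trips without masking malformed input.
#' @export
validate_matrix <- function(x, kind = MATRIX_KINDS) {
  kind <- match.arg(kind)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_domain("expected a numeric matrix", "scaddecon_parse_error")
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop_domain("matrix must have at least one row and one column")
  }
  rid <- rownames(x); cid <- colnames(x)
  if (is.null(rid) || is.null(cid)) {
    stop_domain("matrix must carry row and column identifiers",
                "scaddecon_identifier_error")
  }
  if (anyDuplicated(rid)) {
    stop_domain("duplicate row identifiers", "scaddecon_identifier_error")
  }
  if (anyDuplicated(cid)) {
    stop_domain("duplicate column identifiers", "scaddecon_identifier_error")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop_domain("matrix contains missing or non-finite entries")
  }
  if (any(x < 0)) {
    stop_domain(sprintf("negative entries are not allowed in a %s matrix", kind))
  }
  if (kind %in% c("cellexpr", "signature") && ncol(x) < 2L) {
    stop_domain("cell-type expression matrices need at least 2 cell types")
  }
  if (kind == "signature" && nrow(x) < ncol(x)) {
    stop_domain("signature matrix needs at least as many genes as cell types",
                "scaddecon_identifiability_error")
  }
  if (kind == "proportions") {
    cs <- colSums(x)
    dev <- abs(cs - 1)
    if (any(dev > 0.05)) {
      stop_domain(sprintf(
        "proportions columns deviate from unit sum by up to %.3g (limit 0.05)",
        max(dev)))
    }
    if (any(cs <= 0)) stop_domain("proportions column with zero mass")
    if (any(dev > 1e-6)) {
      warning(sprintf(
        "renormalizing %d proportions column(s) off unit sum by up to %.3g",
        sum(dev > 1e-6), max(dev)), call. = FALSE)
    }
    if (any(dev > 0)) x <- sweep(x, 2L, cs, "/")
  }
  invisible(x)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop_domain("empty file", "scaddecon_parse_error")
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a typed matrix from delimited text
#'
#' Reads a tab- or comma-delimited file (delimiter auto-detected from the
#' header line) whose first column holds row identifiers and whose header
#' row holds column identifiers, and validates it as the requested kind.
#'
#' @inheritParams validate_matrix
#' @param path path to a TSV or CSV file.
#' @return a validated numeric matrix with dimnames; row and column
#'   order are preserved as read.
#' @seealso [write_matrix()], [validate_matrix()]
#' @export
read_matrix <- function(path, kind = MATRIX_KINDS) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_domain(paste0("file not found: ", path),
                                      "scaddecon_io_error")
  sep <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop_domain("no data columns found", "scaddecon_parse_error")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop_domain("duplicate row identifiers", "scaddecon_identifier_error")
  }
  df <- df[, -1L, drop = FALSE]
  rownames(df) <- ids
  not_num <- !vapply(df, is.numeric, logical(1))
  if (any(not_num)) {
    stop_domain(sprintf("non-numeric values in column(s): %s",
                        paste(colnames(df)[not_num], collapse = ", ")),
                "scaddecon_parse_error")
  }
  x <- as.matrix(df)
  x <- validate_matrix(x, kind)
  x
}

#' Write a typed matrix as tab-delimited text
#'
#' Validates the matrix first (invalid matrices are rejected before any
#' write) and writes it with row identifiers in the first column using
#' full double precision, so `read_matrix(write_matrix(x))` reproduces
#' values within 1e-12 and identifiers exactly.
#'
#' @inheritParams validate_matrix
#' @param path output file path; the leading header field names the row
#'   identifier column (`"id"`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, kind = MATRIX_KINDS) {
  kind <- match.arg(kind)
  x <- validate_matrix(x, kind)
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop_domain(paste0("cannot open for writing: ", path), "scaddecon_io_error")
  })
  on.exit(close(con))
  writeLines(paste(c("id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Restrict a bulk matrix to signature genes
#'
#' Subsets the bulk matrix to the signature's genes (by identifier, not
#' position) and reorders both so their rows match. Signature genes
#' absent from the bulk are dropped with a message; if fewer overlapping
#' genes remain than there are cell types the system is unidentifiable
#' and an error is raised.
#'
#' @param bulk genes x samples bulk matrix.
#' @param sig signature matrix (genes x cell types).
#' @return list with elements `bulk` and `sig`, row-aligned.
#' @export
align_genes <- function(bulk, sig) {
  validate_matrix(bulk, "bulk")
  validate_matrix(sig, "signature")
  keep <- rownames(sig) %in% rownames(bulk)
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(sprintf("align_genes: dropping %d signature gene(s) absent from bulk",
                    n_drop))
  }
  genes <- rownames(sig)[keep]
  if (length(genes) < ncol(sig)) {
    stop_domain(sprintf(
      "only %d signature genes overlap the bulk; need at least %d (one per cell type)",
      length(genes), ncol(sig)), "scaddecon_identifiability_error")
  }
  list(bulk = bulk[genes, , drop = FALSE], sig = sig[genes, , drop = FALSE])
}
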