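#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated `name`, `description`, then member
#' gene ids. Duplicate members within a set are removed with a warning;
#' duplicate set names are an error.
#'
#' @param path path to a GMT file.
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `description` attribute per set.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("GMT line ", i, ": fewer than 3 tab-separated fields", call. = FALSE)
    nm[i] <- fields[[1]]
    desc[i] <- fields[[2]]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("GMT set '", nm[i], "': duplicate member ids removed",
              call. = FALSE)
      members <- unique(members)
    }
    if (length(members) == 0L)
      stop("GMT line ", i, " ('", nm[i], "'): no members", call. = FALSE)
    sets[[i]] <- members
  }
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(desc, nm)
  class(sets) <- "gene_set_collection"
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors (a `gene_set_collection`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a numeric feature-by-sample matrix from TSV
#'
#' Dialect: first column row ids, header row of column ids, '.' decimal,
#' empty cell = missing. Non-numeric cells and duplicate row ids are errors.
#'
#' @param path path to a TSV file.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop(path, ": need at least one data column", call. = FALSE)
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop(path, ": duplicate row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  body <- as.matrix(raw[, -1, drop = FALSE])
  out <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(out) & body != "", arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(path, ": non-numeric cell at row '", ids[bad[1, 1]], "', column '",
         colnames(body)[bad[1, 2]], "': \"", body[bad[1, , drop = FALSE]],
         "\"", call. = FALSE)
  nonfinite <- which(!is.na(out) & !is.finite(out), arr.ind = TRUE)
  if (nrow(nonfinite) > 0L)
    stop(path, ": non-finite value at row '", ids[nonfinite[1, 1]], "'",
         call. = FALSE)
  dimnames(out) <- list(ids, colnames(body))
  out
}

#' Write a numeric matrix to TSV
#'
#' Inverse of [read_matrix_tsv()]: missing values become empty cells and
#' numbers are printed at full precision, so write -> read round-trips.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param id_name header label of the row-id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_name = "feature") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  cells <- format(mat, digits = 17, trim = TRUE, scientific = FALSE)
  cells[is.na(mat)] <- ""
  lines <- c(paste(c(id_name, colnames(mat)), collapse = "\t"),
             vapply(seq_len(nrow(mat)), function(i) {
               paste(c(rownames(mat)[i], cells[i, ]), collapse = "\t")
             }, character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
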