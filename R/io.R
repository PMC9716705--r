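# Readers and writers for the plain-text formats the pipelines exchange.
# All numeric output keeps full double precision.

#' Read a phenotype table
#'
#' CSV/TSV with an `id` column first and one column per trait; `NA` cells
#' become zeros in the attached missingness pattern.
#'
#' @param path file path.
#' @return data frame with attribute `"pattern"` (a [missingness_pattern()]
#'   over the trait columns).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, sep = guess_sep(path), stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (ncol(df) < 2) stopf("phenotype file needs an id column and at least one trait")
  for (j in 2:ncol(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(!is.na(df[[j]]) & df[[j]] != "" & is.na(v))
    if (length(bad)) stopf("malformed value in %s at line %d", path, bad[1] + 1L)
    df[[j]] <- v
  }
  r <- unname(1 - is.na(as.matrix(df[, -1, drop = FALSE])) * 1)
  attr(df, "pattern") <- missingness_pattern(r)
  df
}

#' Read a marker matrix
#'
#' CSV/TSV: first column individual id, header row of marker names.
#'
#' @param path file path.
#' @return numeric matrix, individuals in rows (rownames = ids).
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, sep = guess_sep(path), check.names = FALSE)
  ids <- as.character(df[[1]])
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stopf("marker matrix contains missing values")
  rownames(X) <- ids
  X
}

#' Read a dense relationship matrix
#'
#' Dense CSV with an id header row and an id first column; must be square
#' with matching ids.
#'
#' @param path file path.
#' @param kind relationship kind tag (default `"genomic"`).
#' @return a [relationship_matrix()].
#' @export
read_relationship <- function(path, kind = "genomic") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, sep = guess_sep(path), check.names = FALSE)
  ids <- as.character(df[[1]])
  K <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(K) <- "double"
  if (!identical(ids, colnames(K)))
    stopf("id mismatch between rows and columns: %s",
          paste(utils::head(setdiff(ids, colnames(K))), collapse = ", "))
  dimnames(K) <- list(ids, ids)
  relationship_matrix(K, ids = ids, kind = kind)
}

#' Write a relationship matrix as dense CSV
#'
#' @param K a [relationship_matrix()].
#' @param path output file.
#' @export
write_relationship <- function(K, path) {
  stopifnot(inherits(K, "relationship_matrix"))
  df <- data.frame(id = K$ids, K$K, check.names = FALSE)
  colnames(df) <- c("id", K$ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pedigree file
#'
#' Three-column CSV (id, sire, dam); 0, empty or `NA` mean unknown parent.
#'
#' @param path file path.
#' @return data frame with columns id, sire, dam.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, sep = guess_sep(path), stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 3) stopf("pedigree file needs id, sire, dam columns")
  names(df)[1:3] <- c("id", "sire", "dam")
  df[1:3]
}

#' Cross-validate ids between two files' objects
#'
#' @param ids_a,ids_b character vectors.
#' @return invisibly `TRUE`; errors listing offenders on mismatch.
#' @export
check_ids <- function(ids_a, ids_b) {
  extra <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
  if (length(extra))
    stopf("id mismatch between files: %s", paste(utils::head(extra, 10), collapse = ", "))
  invisible(TRUE)
}

guess_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Write chain draws (thinned) as CSV
#'
#' @param chain an [mcmc_chain()].
#' @param path output file.
#' @param thin keep every `thin`-th draw (default 1).
#' @export
write_chain <- function(chain, path, thin = 1) {
  stopifnot(inherits(chain, "mcmc_chain"))
  d <- chain$draws[seq(1, nrow(chain$draws), by = thin), , drop = FALSE]
  utils::write.csv(as.data.frame(d), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
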