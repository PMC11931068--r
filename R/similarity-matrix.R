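#' Square pairwise similarity matrix
#'
#' The common currency of the feature pipeline: a square, symmetric matrix of
#' pairwise similarity scores over an ordered set of entities (drugs or ADR
#' terms), tagged with the feature kind it was derived from. Jaccard-, MeSH-
#' and Tanimoto-kind matrices live in `[0, 1]`; expression-signature cosine
#' similarity (`kind = "ge"`) lives in `[-1, 1]`.
#'
#' @param m numeric square matrix; dimnames are taken as entity ids unless
#'   `ids` is given.
#' @param kind one of `"cs"`, `"ge"`, `"cgi"`, `"mesh"`, `"gda"`,
#'   `"dsa_drug"`, `"dsa_adr"`.
#' @param ids character vector of entity ids in row/column order.
#' @return a `sim_matrix`: a numeric matrix with dimnames and a `kind`
#'   attribute.
#' @export
sim_matrix <- function(m, kind, ids = rownames(m)) {
  kinds <- c("cs", "ge", "cgi", "mesh", "gda", "dsa_drug", "dsa_adr")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds) {
    dga_stop(sprintf("unknown similarity kind; expected one of %s",
                     paste(kinds, collapse = ", ")), "dga_config_error")
  }
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) dga_stop("similarity matrix must be square", "dga_data_error")
  if (is.null(ids)) dga_stop("similarity matrix needs entity ids (dimnames or ids=)",
                             "dga_data_error")
  ids <- as.character(ids)
  if (length(ids) != nrow(m)) dga_stop("ids length does not match matrix size",
                                       "dga_data_error")
  if (anyDuplicated(ids)) dga_stop("duplicate entity ids in similarity matrix",
                                   "dga_data_error")
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) dga_stop("non-finite entries in similarity matrix",
                                   "dga_data_error")
  if (nrow(m) > 0L && max(abs(m - t(m))) > 1e-9) {
    dga_stop("similarity matrix is not symmetric within 1e-9", "dga_data_error")
  }
  lo <- if (kind == "ge") -1 else 0
  if (nrow(m) > 0L && (min(m) < lo - 1e-9 || max(m) > 1 + 1e-9)) {
    dga_stop(sprintf("entries outside [%g, 1] for kind '%s'", lo, kind),
             "dga_data_error")
  }
  dimnames(m) <- list(ids, ids)
  structure(m, kind = kind, class = c("sim_matrix", class(m)))
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("<sim_matrix kind=%s, %d x %d entities>\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  if (nrow(x) > 0L) {
    k <- min(6L, nrow(x))
    print(unclass(x)[seq_len(k), seq_len(k), drop = FALSE], digits = 4)
    if (nrow(x) > k) cat(sprintf("... %d more entities\n", nrow(x) - k))
  }
  invisible(x)
}

#' @rdname sim_matrix
#' @param x object to test.
#' @export
is_sim_matrix <- function(x) inherits(x, "sim_matrix")

#' Kind tag of a similarity matrix
#' @param x a [sim_matrix()].
#' @return the kind string.
#' @export
sim_kind <- function(x) attr(x, "kind")

#' Read and write similarity matrices as TSV
#'
#' The on-disk form is a tab-separated table with a header row of entity ids
#' and the ids repeated in the first column, so the file round-trips through
#' any spreadsheet or `data.table::fread()`.
#'
#' @param x a [sim_matrix()].
#' @param path file path.
#' @param kind kind tag to stamp on the loaded matrix; when `NULL` it is
#'   recovered from the `# kind:` comment line written by [write_sim_matrix()].
#' @return `write_sim_matrix()` returns `path` invisibly; `read_sim_matrix()`
#'   returns a [sim_matrix()].
#' @export
write_sim_matrix <- function(x, path) {
  stopifnot(is_sim_matrix(x))
  atomic_write(path, function(tmp) {
    writeLines(sprintf("# kind: %s", sim_kind(x)), tmp)
    dt <- data.table::data.table(id = rownames(x))
    for (j in seq_len(ncol(x))) dt[[colnames(x)[j]]] <- unclass(x)[, j]
    data.table::fwrite(dt, tmp, sep = "\t", append = TRUE, col.names = TRUE)
  })
}

#' @rdname write_sim_matrix
#' @export
read_sim_matrix <- function(path, kind = NULL) {
  if (is.null(kind)) {
    first <- readLines(path, n = 1L)
    if (grepl("^# kind: ", first)) kind <- sub("^# kind: ", "", first)
    else dga_stop("no kind tag in file and none supplied", "dga_config_error")
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = "id\t")
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  # guard against asymmetric rounding introduced by serialization
  m <- (m + t(m)) / 2
  sim_matrix(m, kind = kind, ids = ids)
}
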