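# Drug-drug similarity features: fingerprint Tanimoto (CS), expression-
# signature cosine (GE) and chemical-gene-interaction Jaccard (CGI).

#' Per-drug gene sets from a CGI table
#'
#' Groups a chemical-gene interaction table into one gene set per drug. A drug
#' listed in `drug_order` but absent from the table gets an empty set (the
#' strict mode of the similarity builders can reject such drugs instead).
#'
#' @param cgi data.frame from [read_cgi()].
#' @param drug_order optional character vector fixing the drugs (and their
#'   order); defaults to the drugs present in the table.
#' @return named list: drug id -> character vector of gene symbols.
#' @export
drug_gene_sets <- function(cgi, drug_order = NULL) {
  sets <- split(cgi$gene_symbol, factor(cgi$chemical_id))
  if (is.null(drug_order)) return(lapply(sets, unique))
  out <- stats::setNames(vector("list", length(drug_order)), drug_order)
  for (d in drug_order) out[[d]] <- unique(sets[[d]]) %||% character()
  out
}

# Shared Jaccard machinery: sets as a binary incidence matrix, similarity via
# one cross-product. Empty-vs-anything pairs are 0 off-diagonal, 1 on the
# diagonal (strict mode errors on empty sets instead).
jaccard_from_sets <- function(sets, order, kind, strict = FALSE) {
  missing <- setdiff(order, names(sets))
  if (length(missing) > 0L) {
    dga_stop(sprintf("no gene set for: %s", paste(missing, collapse = ", ")),
             "dga_lookup_error")
  }
  sets <- sets[order]
  sizes <- lengths(sets)
  if (strict && any(sizes == 0L)) {
    dga_stop(sprintf("empty feature set(s) in strict mode: %s",
                     paste(order[sizes == 0L], collapse = ", ")),
             "dga_data_error")
  }
  universe <- unique(unlist(sets, use.names = FALSE))
  n <- length(order)
  if (length(universe) == 0L) {
    m <- diag(nrow = n)
    return(sim_matrix(m, kind = kind, ids = order))
  }
  inc <- matrix(0, nrow = n, ncol = length(universe))
  for (i in seq_len(n)) inc[i, match(sets[[i]], universe)] <- 1
  inter <- tcrossprod(inc)
  union <- outer(sizes, sizes, "+") - inter
  m <- ifelse(union > 0, inter / pmax(union, 1), 0)
  diag(m) <- 1
  sim_matrix(m, kind = kind, ids = order)
}

#' Tanimoto similarity of binary fingerprints
#'
#' Pairwise Tanimoto coefficient `x_i.x_j / (|x_i|^2 + |x_j|^2 - x_i.x_j)`
#' over a drugs x bits 0/1 matrix. On binary vectors this equals the Jaccard
#' index of the bit-support sets. An all-zero fingerprint gets similarity 0 to
#' everything and 1 to itself (with a warning); `strict = TRUE` errors
#' instead.
#'
#' @param fps integer/numeric 0/1 matrix, rows = drugs (rownames = ids).
#' @param strict error on all-zero fingerprints instead of the 0/1 convention.
#' @return a [sim_matrix()] of kind `"cs"`.
#' @export
tanimoto_similarity <- function(fps, strict = FALSE) {
  fps <- as.matrix(fps)
  if (nrow(fps) < 1L) dga_stop("need at least one drug", "dga_data_error")
  if (!all(fps %in% c(0, 1))) dga_stop("fingerprints must be binary",
                                       "dga_data_error")
  storage.mode(fps) <- "double"
  sizes <- rowSums(fps)
  if (any(sizes == 0)) {
    if (strict) dga_stop(sprintf("all-zero fingerprint(s): %s",
                                 paste(rownames(fps)[sizes == 0], collapse = ", ")),
                         "dga_data_error")
    warning("all-zero fingerprint(s); similarity set to 0 off-diagonal")
  }
  inter <- tcrossprod(fps)
  denom <- outer(sizes, sizes, "+") - inter
  m <- ifelse(denom > 0, inter / pmax(denom, 1), 0)
  diag(m) <- 1
  sim_matrix(m, kind = "cs", ids = rownames(fps))
}

#' Cosine similarity of expression signatures
#'
#' Pairwise cosine similarity `x_i.x_j / (||x_i|| ||x_j||)` over a drugs x
#' genes signature matrix (e.g. drug-perturbed differential expression in the
#' landmark-gene space). Entries lie in `[-1, 1]`. A zero-norm signature gets
#' similarity 0 to everything and 1 to itself (warning), or an error when
#' `strict = TRUE`.
#'
#' @param ge numeric matrix, rows = drugs (rownames = ids), finite entries.
#' @param strict error on zero-norm signatures.
#' @return a [sim_matrix()] of kind `"ge"`.
#' @export
cosine_similarity_ge <- function(ge, strict = FALSE) {
  ge <- as.matrix(ge)
  if (nrow(ge) < 1L || ncol(ge) < 1L) dga_stop("empty signature matrix",
                                               "dga_data_error")
  if (any(!is.finite(ge))) dga_stop("non-finite signature entries",
                                    "dga_data_error")
  nrm <- sqrt(rowSums(ge^2))
  if (any(nrm == 0)) {
    if (strict) dga_stop(sprintf("zero-norm signature(s): %s",
                                 paste(rownames(ge)[nrm == 0], collapse = ", ")),
                         "dga_data_error")
    warning("zero-norm signature(s); similarity set to 0 off-diagonal")
  }
  safe <- ifelse(nrm > 0, nrm, 1)
  x <- ge / safe
  m <- tcrossprod(x)
  m[nrm == 0, ] <- 0
  m[, nrm == 0] <- 0
  m <- pmin(pmax((m + t(m)) / 2, -1), 1)
  diag(m) <- 1
  sim_matrix(m, kind = "ge", ids = rownames(ge))
}

#' Jaccard similarity of drug gene-interaction sets
#'
#' Pairwise Jaccard index `|GT_i n GT_j| / |GT_i u GT_j|` over the per-drug
#' gene sets of a chemical-gene interaction table. Interaction direction and
#' cell type are deliberately ignored: a gene either interacts with the drug
#' or it does not.
#'
#' @param sets named list from [drug_gene_sets()].
#' @param drug_order character vector of drug ids covering all drugs to
#'   featurize, in output order.
#' @param strict error on drugs with empty gene sets.
#' @return a [sim_matrix()] of kind `"cgi"`.
#' @export
jaccard_similarity_cgi <- function(sets, drug_order = names(sets), strict = FALSE) {
  jaccard_from_sets(sets, drug_order, kind = "cgi", strict = strict)
}

#' Binary fingerprints from SMILES strings
#'
#' Converts SMILES to binary structural fingerprints through the OpenBabel
#' backend (package \pkg{ChemmineOB}): `"topological"` gives the 1024-bit
#' path-based FP2 fingerprint, `"maccs"` the 166 MACCS structural keys
#' (OpenBabel pads MACCS to 256 bits; the pad is dropped). Unparseable SMILES
#' are dropped with a warning and listed in the `dropped` attribute.
#'
#' @param smiles named character vector (names = drug ids).
#' @param kind `"topological"` or `"maccs"`.
#' @return 0/1 integer matrix, rows named by drug id, with attribute
#'   `dropped` (character vector of drug ids that failed to parse).
#' @export
fingerprints_from_smiles <- function(smiles, kind = c("topological", "maccs")) {
  kind <- match.arg(kind)
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    dga_stop("fingerprints_from_smiles needs the ChemmineOB package",
             "dga_config_error")
  }
  if (is.null(names(smiles)) || any(!nzchar(names(smiles)))) {
    dga_stop("smiles must be a named vector (names = drug ids)",
             "dga_config_error")
  }
  fpname <- switch(kind, topological = "FP2", maccs = "MACCS")
  rows <- list()
  dropped <- character()
  for (id in names(smiles)) {
    fp <- tryCatch({
      mol <- ChemmineOB::forEachMol("SMILES",
                                    paste0(smiles[[id]], "\t", id), identity)
      as.numeric(ChemmineOB::fingerprint_OB(mol, fpname))
    }, error = function(e) NULL)
    if (is.null(fp)) dropped <- c(dropped, id) else rows[[id]] <- fp
  }
  if (length(dropped) > 0L) {
    warning(sprintf("dropped %d unparseable SMILES: %s", length(dropped),
                    paste(dropped, collapse = ", ")))
  }
  if (length(rows) == 0L) dga_stop("no SMILES could be parsed", "dga_data_error")
  m <- do.call(rbind, rows)
  if (kind == "maccs" && ncol(m) >= 166L) m <- m[, seq_len(166L), drop = FALSE]
  storage.mode(m) <- "integer"
  rownames(m) <- names(rows)
  attr(m, "dropped") <- dropped
  m
}
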