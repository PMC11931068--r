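# Assembling per-entity feature vectors from similarity blocks, the masked
# association-profile (DSA) neighbourhood feature, and the feature cross.

#' Concatenate similarity blocks into per-entity feature rows
#'
#' Each entity's feature vector is the concatenation of its similarity rows
#' across the given blocks, e.g. `Drug = (Sim_CS, Sim_GE, Sim_CGI)` and
#' `Side = (Sim_MESH, Sim_GDA)`. All blocks must be square over the same
#' entity ids.
#'
#' @param blocks named list of [sim_matrix()] objects over identical ids.
#' @param order character vector of entity ids fixing the row order; defaults
#'   to the first block's order.
#' @return a numeric matrix (entities x total width) with rownames = ids and
#'   attribute `block_map`: a named list of column index spans, one per block.
#' @export
assemble_features <- function(blocks, order = NULL) {
  if (length(blocks) == 0L) dga_stop("no feature blocks given", "dga_config_error")
  if (is.null(names(blocks)) || any(!nzchar(names(blocks)))) {
    names(blocks) <- vapply(blocks, sim_kind, character(1))
  }
  ids0 <- sort(rownames(blocks[[1L]]))
  for (k in names(blocks)) {
    b <- blocks[[k]]
    if (!is_sim_matrix(b)) dga_stop(sprintf("block '%s' is not a sim_matrix", k),
                                    "dga_config_error")
    if (!identical(sort(rownames(b)), ids0)) {
      dga_stop(sprintf("entity ids of block '%s' differ from block '%s'",
                       k, names(blocks)[1L]), "dga_data_error")
    }
  }
  order <- order %||% rownames(blocks[[1L]])
  if (!setequal(order, ids0)) {
    dga_stop("requested order does not cover the blocks' entity ids",
             "dga_data_error")
  }
  mats <- lapply(blocks, function(b) unclass(b)[order, order, drop = FALSE])
  out <- do.call(cbind, mats)
  rownames(out) <- order
  widths <- vapply(mats, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  attr(out, "block_map") <- stats::setNames(
    lapply(seq_along(widths), function(i) starts[i]:ends[i]), names(blocks))
  out
}

#' Association-profile (DSA neighbourhood) similarity with held-out masking
#'
#' Builds the binary drug x ADR association matrix from known positive pairs,
#' forces the entries of all `mask` pairs to zero, and returns the Jaccard
#' similarity of row profiles (`axis = "drug"`) or column profiles
#' (`axis = "adr"`). Masking the current fold's held-out pairs before feature
#' construction is what keeps this neighbourhood feature free of
#' train-test contamination.
#'
#' @param assoc data.frame with columns `drug_id`, `adr_id`, `label`; rows
#'   with `label == 1` define the association matrix.
#' @param mask data.frame of held-out `(drug_id, adr_id)` pairs whose entries
#'   are zeroed before similarity computation (may be empty).
#' @param axis `"drug"` for drug-drug or `"adr"` for ADR-ADR similarity.
#' @param drugs,adrs entity universes (and output order); default to the
#'   entities present in `assoc`.
#' @return a [sim_matrix()] of kind `"dsa_drug"` or `"dsa_adr"`, with the
#'   masked association matrix in attribute `assoc_matrix`.
#' @export
dsa_profile_similarity <- function(assoc, mask = NULL,
                                   axis = c("drug", "adr"),
                                   drugs = NULL, adrs = NULL) {
  axis <- match.arg(axis)
  drugs <- drugs %||% sort(unique(assoc$drug_id))
  adrs <- adrs %||% sort(unique(assoc$adr_id))
  A <- matrix(0, nrow = length(drugs), ncol = length(adrs),
              dimnames = list(drugs, adrs))
  pos <- assoc[assoc$label == 1L, , drop = FALSE]
  keep <- pos$drug_id %in% drugs & pos$adr_id %in% adrs
  A[cbind(match(pos$drug_id[keep], drugs), match(pos$adr_id[keep], adrs))] <- 1
  if (!is.null(mask) && nrow(mask) > 0L) {
    mk <- mask$drug_id %in% drugs & mask$adr_id %in% adrs
    A[cbind(match(mask$drug_id[mk], drugs), match(mask$adr_id[mk], adrs))] <- 0
  }
  kind <- if (axis == "drug") "dsa_drug" else "dsa_adr"
  X <- if (axis == "drug") A else t(A)
  sizes <- rowSums(X)
  inter <- tcrossprod(X)
  denom <- outer(sizes, sizes, "+") - inter
  m <- ifelse(denom > 0, inter / pmax(denom, 1), 0)
  diag(m) <- 1
  out <- sim_matrix(m, kind = kind, ids = rownames(X))
  attr(out, "assoc_matrix") <- A
  out
}

#' Feature cross of a drug and an ADR feature vector
#'
#' The Cartesian feature cross realized as the scalar outer product: cell
#' `(a, b)` holds `d_a * s_b`. With projection matrices given, `d` and `s` are
#' first reduced linearly (`t(proj) %*% x`), bounding the cross size for the
#' convolutional subnetwork; inside the model these projections are trained
#' parameters.
#'
#' @param d numeric drug feature vector.
#' @param s numeric ADR feature vector.
#' @param proj_d,proj_s optional projection matrices (`length(d) x m`,
#'   `length(s) x n`).
#' @return numeric matrix of shape `(|d|, |s|)` (or projected dims).
#' @export
feature_cross <- function(d, s, proj_d = NULL, proj_s = NULL) {
  if (length(d) == 0L || length(s) == 0L) {
    dga_stop("zero-length feature vector in feature cross", "dga_data_error")
  }
  if (any(!is.finite(d)) || any(!is.finite(s))) {
    dga_stop("non-finite feature values in feature cross", "dga_data_error")
  }
  if (!is.null(proj_d)) d <- as.numeric(crossprod(proj_d, d))
  if (!is.null(proj_s)) s <- as.numeric(crossprod(proj_s, s))
  outer(as.numeric(d), as.numeric(s))
}
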