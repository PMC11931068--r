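# ADR-ADR similarity features: DAG semantic similarity over a MeSH-style
# hierarchy, and gene-disease-association Jaccard.

#' Semantic contributions of a term's ancestor closure
#'
#' For an ADR term `s` in an ontology DAG, computes the semantic contribution
#' `C_s(n)` of every node `n` in its ancestor closure `N_s` (the term plus all
#' ancestors): `C_s(s) = 1`, and for any other node the contribution decays by
#' the factor `delta` per edge along the best path, i.e.
#' `C_s(n) = max over children n' of delta * C_s(n')`. Contributions of a
#' descriptor reachable along several address chains take the maximum over
#' paths automatically.
#'
#' @param dag an [ontology_dag()].
#' @param s node id of the ADR term.
#' @param delta semantic contribution factor in (0, 1]; 0.5 is the
#'   conventional value.
#' @return named numeric vector `C_s(n)` over the closure, `s` first.
#' @export
semantic_contributions <- function(dag, s, delta = 0.5) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 1) {
    dga_stop("delta must be in (0, 1]", "dga_config_error")
  }
  if (!s %in% dag$nodes) {
    dga_stop(sprintf("ADR term '%s' not found in ontology", s),
             "dga_lookup_error")
  }
  contrib <- stats::setNames(1, s)
  queue <- s
  while (length(queue) > 0L) {
    n <- queue[1L]; queue <- queue[-1L]
    cand <- delta * contrib[[n]]
    for (p in dag$parents[[n]]) {
      if (is.na(contrib[p]) || cand > contrib[[p]]) {
        contrib[p] <- cand
        queue <- c(queue, p)
      }
    }
  }
  contrib
}

#' Semantic value of an ADR term
#'
#' The sum of semantic contributions over the term's ancestor closure,
#' `DV(s) = sum_n C_s(n)`. Always >= 1 because the term contributes 1 to
#' itself.
#'
#' @param closure named numeric vector from [semantic_contributions()].
#' @return scalar semantic value.
#' @export
semantic_value <- function(closure) {
  if (length(closure) == 0L || any(closure <= 0) || any(closure > 1)) {
    dga_stop("invalid closure: contributions must be in (0, 1]", "dga_data_error")
  }
  sum(closure)
}

#' DAG semantic similarity of ADR terms
#'
#' Pairwise semantic similarity over a MeSH-style hierarchy:
#' `Sim(s_i, s_j) = sum over shared closure nodes of (C_si(n) + C_sj(n)) /
#' (DV(s_i) + DV(s_j))`. Terms sharing more (and closer) ancestors score
#' higher; the diagonal is exactly 1.
#'
#' @param dag an [ontology_dag()].
#' @param adrs character vector of ADR node ids, in output order.
#' @param delta semantic contribution factor in (0, 1].
#' @param strict if `TRUE` (default) an ADR missing from the ontology is an
#'   error; if `FALSE` it is treated as an isolated node (similarity 0 to all
#'   others, 1 to itself).
#' @return a [sim_matrix()] of kind `"mesh"`.
#' @export
mesh_semantic_similarity <- function(dag, adrs, delta = 0.5, strict = TRUE) {
  if (anyDuplicated(adrs)) dga_stop("duplicate ADR ids", "dga_data_error")
  present <- adrs %in% dag$nodes
  if (strict && !all(present)) {
    dga_stop(sprintf("ADR term(s) not in ontology: %s",
                     paste(adrs[!present], collapse = ", ")),
             "dga_lookup_error")
  }
  closures <- vector("list", length(adrs))
  for (i in seq_along(adrs)) {
    closures[[i]] <- if (present[i]) {
      semantic_contributions(dag, adrs[i], delta)
    } else {
      stats::setNames(1, adrs[i])  # isolated node: closure is itself
    }
  }
  dv <- vapply(closures, sum, numeric(1))
  n <- length(adrs)
  m <- diag(nrow = n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      ci <- closures[[i]]
      for (j in seq((i + 1L), n)) {
        cj <- closures[[j]]
        shared <- intersect(names(ci), names(cj))
        if (length(shared) > 0L) {
          m[i, j] <- m[j, i] <- sum(ci[shared] + cj[shared]) / (dv[i] + dv[j])
        }
      }
    }
  }
  sim_matrix(m, kind = "mesh", ids = adrs)
}

#' Per-ADR gene sets from a GDA table
#'
#' Groups a gene-disease association table into one gene set per ADR (disease
#' term). ADRs listed in `adr_order` but absent from the table get empty sets.
#'
#' @param gda data.frame from [read_gda()].
#' @param adr_order optional character vector fixing the ADRs and their order.
#' @return named list: adr id -> character vector of gene symbols.
#' @export
adr_gene_sets <- function(gda, adr_order = NULL) {
  sets <- split(gda$gene_symbol, factor(gda$disease_id))
  if (is.null(adr_order)) return(lapply(sets, unique))
  out <- stats::setNames(vector("list", length(adr_order)), adr_order)
  for (a in adr_order) out[[a]] <- unique(sets[[a]]) %||% character()
  out
}

#' Jaccard similarity of ADR gene-association sets
#'
#' Pairwise Jaccard index `|GS_i n GS_j| / |GS_i u GS_j|` over the per-ADR
#' gene sets of a gene-disease association table. Evidence type
#' (marker/mechanism/therapeutic) is not weighted.
#'
#' @param sets named list from [adr_gene_sets()].
#' @param adr_order character vector of ADR ids, in output order.
#' @param strict error on ADRs with empty gene sets.
#' @return a [sim_matrix()] of kind `"gda"`.
#' @export
jaccard_similarity_gda <- function(sets, adr_order = names(sets), strict = FALSE) {
  jaccard_from_sets(sets, adr_order, kind = "gda", strict = strict)
}
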