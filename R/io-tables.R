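# Readers for the five input table dialects. All are tab-separated text with
# a header row; lines starting with '#' are treated as comments (CTD dumps
# carry such preamble). Identifiers are compared verbatim: gene symbols are
# case-meaningful, so no case folding anywhere.

read_delim_table <- function(path, sep = "\t") {
  if (!file.exists(path)) dga_stop(sprintf("file not found: %s", path), "dga_config_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(data.table::data.table())
  data.table::fread(text = lines, sep = sep, header = TRUE,
                    colClasses = "character", na.strings = NULL)
}

check_columns <- function(dt, cols, path) {
  missing <- setdiff(cols, names(dt))
  if (length(missing) > 0L) {
    dga_stop(sprintf("column(s) %s not found in %s (have: %s)",
                     paste(sQuote(missing), collapse = ", "), path,
                     paste(names(dt), collapse = ", ")),
             "dga_config_error")
  }
}

dedup_pairs <- function(dt, key1, key2, filter = NULL) {
  raw <- nrow(dt)
  if (raw > 0L && !is.null(filter)) {
    keep <- vapply(seq_len(nrow(dt)), function(i) isTRUE(filter(dt[i, ])), logical(1))
    dt <- dt[keep, ]
  }
  filtered <- nrow(dt)
  if (filtered > 0L) {
    out <- unique(dt[, c(key1, key2), with = FALSE])
    if (any(!nzchar(out[[key1]])) || any(!nzchar(out[[key2]]))) {
      dga_stop(sprintf("empty %s or %s key", key1, key2), "dga_data_error")
    }
  } else {
    out <- data.table::data.table(a = character(), b = character())
    data.table::setnames(out, c(key1, key2))
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  attr(out, "report") <- list(raw_rows = raw, filtered_rows = filtered,
                              unique_rows = nrow(out),
                              dropped_duplicates = filtered - nrow(out))
  out
}

#' Read a chemical-gene interaction (CGI) table
#'
#' Loads a CTD-style chemical-gene interaction dump and reduces it to unique
#' `(chemical_id, gene_symbol)` pairs; all other columns (Organism,
#' Interaction, InteractionActions, PubMedIDs, ...) are ignored, so records
#' differing only in those collapse to one pair. The per-drug gene sets built
#' from this table drive the CGI Jaccard similarity.
#'
#' @param path delimited text file with a header row; `#` comment lines are
#'   skipped.
#' @param chemical_col,gene_col header names of the chemical and gene columns.
#' @param sep field separator.
#' @param filter optional predicate applied to each raw row (a one-row
#'   data.table) before deduplication, e.g. to drop interaction classes.
#' @return a data.frame with columns `chemical_id`, `gene_symbol` and a
#'   `report` attribute (`raw_rows`, `unique_rows`, `dropped_duplicates`).
#' @export
read_cgi <- function(path, chemical_col = "ChemicalID", gene_col = "GeneSymbol",
                     sep = "\t", filter = NULL) {
  dt <- read_delim_table(path, sep)
  if (nrow(dt) == 0L && ncol(dt) == 0L) {
    warning("empty CGI file: ", path)
    out <- data.frame(chemical_id = character(), gene_symbol = character())
    attr(out, "report") <- list(raw_rows = 0L, filtered_rows = 0L,
                                unique_rows = 0L, dropped_duplicates = 0L)
    return(out)
  }
  check_columns(dt, c(chemical_col, gene_col), path)
  out <- dedup_pairs(dt, chemical_col, gene_col, filter)
  names(out) <- c("chemical_id", "gene_symbol")
  rep <- attr(out, "report")
  message(sprintf("read_cgi: %d raw rows -> %d unique (chemical, gene) pairs",
                  rep$raw_rows, rep$unique_rows))
  out
}

#' Read a gene-disease association (GDA) table
#'
#' As [read_cgi()], with the roles swapped: unique `(gene_symbol, disease_id)`
#' pairs, ignoring DirectEvidence, InferenceScore and other columns. The
#' per-ADR gene sets built from this table drive the GDA Jaccard similarity.
#'
#' @inheritParams read_cgi
#' @param gene_col,disease_col header names of the gene and disease columns.
#' @return a data.frame with columns `gene_symbol`, `disease_id` and a
#'   `report` attribute.
#' @export
read_gda <- function(path, gene_col = "GeneSymbol", disease_col = "DiseaseID",
                     sep = "\t", filter = NULL) {
  dt <- read_delim_table(path, sep)
  if (nrow(dt) == 0L && ncol(dt) == 0L) {
    warning("empty GDA file: ", path)
    out <- data.frame(gene_symbol = character(), disease_id = character())
    attr(out, "report") <- list(raw_rows = 0L, filtered_rows = 0L,
                                unique_rows = 0L, dropped_duplicates = 0L)
    return(out)
  }
  check_columns(dt, c(gene_col, disease_col), path)
  out <- dedup_pairs(dt, gene_col, disease_col, filter)
  names(out) <- c("gene_symbol", "disease_id")
  rep <- attr(out, "report")
  message(sprintf("read_gda: %d raw rows -> %d unique (gene, disease) pairs",
                  rep$raw_rows, rep$unique_rows))
  out
}

#' Read a drug-ADR association table
#'
#' Two- or three-column delimited text `(drug, adr[, label])`. A missing label
#' column means every listed pair is a known positive (label 1), the SIDER
#' convention. Duplicate pairs with conflicting labels are a data error.
#'
#' @inheritParams read_cgi
#' @return a data.frame with columns `drug_id`, `adr_id`, `label` (integer
#'   0/1), one row per unique pair.
#' @export
read_associations <- function(path, sep = "\t") {
  dt <- read_delim_table(path, sep)
  if (nrow(dt) == 0L && ncol(dt) == 0L) {
    return(data.frame(drug_id = character(), adr_id = character(),
                      label = integer()))
  }
  if (ncol(dt) < 2L) dga_stop("association table needs at least two columns",
                              "dga_data_error")
  out <- data.frame(drug_id = dt[[1L]], adr_id = dt[[2L]],
                    stringsAsFactors = FALSE)
  if (ncol(dt) >= 3L) {
    lab <- suppressWarnings(as.integer(dt[[3L]]))
    if (any(is.na(lab)) || !all(lab %in% c(0L, 1L))) {
      dga_stop("labels must be 0 or 1", "dga_data_error")
    }
    out$label <- lab
  } else {
    out$label <- 1L
  }
  if (any(!nzchar(out$drug_id)) || any(!nzchar(out$adr_id))) {
    dga_stop("empty drug or ADR id", "dga_data_error")
  }
  key <- paste(out$drug_id, out$adr_id, sep = "\r")
  agg <- tapply(out$label, key, function(x) length(unique(x)))
  bad <- names(agg)[agg > 1L]
  if (length(bad) > 0L) {
    dga_stop(sprintf("conflicting labels for pair(s): %s",
                     paste(gsub("\r", " / ", bad), collapse = "; ")),
             "dga_data_error")
  }
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a drug x gene expression-signature matrix
#'
#' Dense numeric matrix: first column drug id, remaining columns the signature
#' dimensions (e.g. 978 landmark genes). Signatures are consumed precomputed;
#' no signature processing happens here.
#'
#' @inheritParams read_cgi
#' @return numeric matrix, rows named by drug id.
#' @export
read_ge_signatures <- function(path, sep = "\t") {
  dt <- read_delim_table(path, sep)
  if (nrow(dt) == 0L) dga_stop("empty signature file", "dga_data_error")
  ids <- dt[[1L]]
  if (anyDuplicated(ids)) {
    dga_stop(sprintf("duplicate drug id(s) in signature matrix: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "dga_data_error")
  }
  m <- suppressWarnings(
    vapply(dt[, -1L, with = FALSE], as.numeric, numeric(nrow(dt))))
  m <- matrix(as.numeric(m), nrow = nrow(dt),
              dimnames = list(ids, names(dt)[-1L]))
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    dga_stop(sprintf("non-finite signature value(s), first at row %d ('%s')",
                     bad[1L, 1L], ids[bad[1L, 1L]]), "dga_data_error")
  }
  m
}

#' Read a drug x bits fingerprint matrix
#'
#' Same dialect as [read_ge_signatures()] but entries must be 0/1.
#'
#' @inheritParams read_cgi
#' @return integer 0/1 matrix, rows named by drug id.
#' @export
read_fingerprints <- function(path, sep = "\t") {
  m <- read_ge_signatures(path, sep)
  if (!all(m %in% c(0, 1))) dga_stop("fingerprint entries must be 0/1",
                                     "dga_data_error")
  storage.mode(m) <- "integer"
  m
}

#' Read drug SMILES strings
#'
#' Two-column table `(drug_id, smiles)`.
#'
#' @inheritParams read_cgi
#' @return named character vector of SMILES, names = drug ids.
#' @export
read_smiles <- function(path, sep = "\t") {
  dt <- read_delim_table(path, sep)
  if (ncol(dt) < 2L) dga_stop("SMILES table needs two columns", "dga_data_error")
  stats::setNames(dt[[2L]], dt[[1L]])
}

# --- writers (mirrors of the readers; used by the simulator and the CLI) ----

write_table_tsv <- function(df, path) {
  atomic_write(path, function(tmp) {
    data.table::fwrite(data.table::as.data.table(df), tmp, sep = "\t")
  })
}

#' Write pipeline tables as TSV
#'
#' Mirror writers for the [read_cgi()]-family readers, used by the synthetic
#' generator and the command-line interface. Matrices are written with the
#' entity id as the first column.
#'
#' @param x the object to write.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cgi <- function(x, path) {
  write_table_tsv(data.frame(ChemicalID = x$chemical_id,
                             GeneSymbol = x$gene_symbol), path)
}

#' @rdname write_cgi
#' @export
write_gda <- function(x, path) {
  write_table_tsv(data.frame(GeneSymbol = x$gene_symbol,
                             DiseaseID = x$disease_id), path)
}

#' @rdname write_cgi
#' @export
write_associations <- function(x, path) {
  write_table_tsv(data.frame(drug_id = x$drug_id, adr_id = x$adr_id,
                             label = x$label), path)
}

#' @rdname write_cgi
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(id = rownames(x), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(x))) df[[colnames(x)[j] %||% paste0("V", j)]] <- x[, j]
  write_table_tsv(df, path)
}
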