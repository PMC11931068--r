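#' MeSH-style ontology DAG
#'
#' A directed acyclic graph of descriptors. Each node may carry several
#' dot-delimited tree addresses (a descriptor such as "Angioedema" sits at
#' three different places in the MeSH hierarchy); descriptors sharing an id
#' merge into a single node whose parent set is the union over addresses.
#'
#' @param parents named list: node id -> character vector of parent node ids.
#' @param addresses named list: node id -> character vector of tree addresses
#'   (may be empty for synthetic nodes).
#' @param synthetic character vector of synthetic category-root ids.
#' @return an `ontology_dag` object.
#' @export
ontology_dag <- function(parents,
                         addresses = stats::setNames(vector("list", length(parents)),
                                                     names(parents)),
                         synthetic = character()) {
  nodes <- names(parents)
  if (is.null(nodes) || anyDuplicated(nodes)) {
    dga_stop("parents must be a named list with unique node ids", "dga_data_error")
  }
  parents <- lapply(parents, function(p) unique(as.character(p)))
  unknown <- setdiff(unlist(parents), nodes)
  if (length(unknown) > 0L) {
    dga_stop(sprintf("parent id(s) not in node set: %s",
                     paste(unknown, collapse = ", ")), "dga_data_error")
  }
  dag <- structure(list(nodes = nodes, parents = parents,
                        addresses = addresses, synthetic = synthetic),
                   class = "ontology_dag")
  if (is.na(topo_order(dag)[1L]) && length(nodes) > 0L) {
    dga_stop("ontology graph contains a cycle", "dga_data_error")
  }
  dag
}

# Kahn topological order, roots first (parents before children);
# NA signals a cycle.
topo_order <- function(dag) {
  n <- length(dag$nodes)
  if (n == 0L) return(character())
  idx <- stats::setNames(seq_len(n), dag$nodes)
  children <- vector("list", n)      # parent index -> child indices
  for (i in seq_len(n)) {
    for (p in dag$parents[[i]]) {
      j <- idx[[p]]
      children[[j]] <- c(children[[j]], i)
    }
  }
  npar_left <- lengths(dag$parents)
  queue <- which(npar_left == 0L)
  done <- integer(0)
  while (length(queue) > 0L) {
    i <- queue[1L]; queue <- queue[-1L]
    done <- c(done, i)
    for (ch in children[[i]]) {
      npar_left[ch] <- npar_left[ch] - 1L
      if (npar_left[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(done) < n) return(NA_character_)
  dag$nodes[done]
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag: %d nodes, %d edges, %d synthetic root(s)>\n",
              length(x$nodes), sum(lengths(x$parents)), length(x$synthetic)))
  invisible(x)
}

#' @rdname ontology_dag
#' @param x object to test.
#' @export
is_ontology_dag <- function(x) inherits(x, "ontology_dag")

#' Number of parent edges in an ontology DAG
#' @param dag an [ontology_dag()].
#' @return integer edge count.
#' @export
n_edges <- function(dag) sum(lengths(dag$parents))

#' Proper ancestors of a node
#' @param dag an [ontology_dag()].
#' @param id node id.
#' @return character vector of ancestor ids (excluding `id`).
#' @export
ancestors <- function(dag, id) {
  if (!id %in% dag$nodes) dga_stop(sprintf("node '%s' not in ontology", id),
                                   "dga_lookup_error")
  seen <- character()
  frontier <- dag$parents[[id]]
  while (length(frontier) > 0L) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier])), seen)
  }
  seen
}

#' Read a MeSH-style descriptor tree table into an ontology DAG
#'
#' Two-column delimited text: `descriptor_id`, `tree_address`, one address per
#' row. Descriptor X is a parent of descriptor Y iff some address of X equals
#' some address of Y with its last dot-segment removed. Descriptors with
#' several addresses merge into one node. An address whose parent address maps
#' to no descriptor is attached to a synthetic root for its top-level category
#' (with a warning), so categories such as "C14" always terminate the DAG.
#'
#' @inheritParams read_cgi
#' @return an [ontology_dag()].
#' @export
read_mesh_tree <- function(path, sep = "\t") {
  dt <- read_delim_table(path, sep)
  if (nrow(dt) == 0L) {
    return(ontology_dag(stats::setNames(list(), character())))
  }
  if (ncol(dt) < 2L) dga_stop("MeSH tree table needs two columns", "dga_data_error")
  desc <- as.character(dt[[1L]])
  addr <- as.character(dt[[2L]])
  if (any(!nzchar(desc)) || any(!nzchar(addr))) {
    dga_stop("empty descriptor id or tree address", "dga_data_error")
  }
  addr_to_desc <- stats::setNames(desc, addr)
  if (anyDuplicated(addr)) {
    dup <- unique(addr[duplicated(addr)])
    conflicting <- vapply(dup, function(a) length(unique(desc[addr == a])) > 1L,
                          logical(1))
    if (any(conflicting)) {
      dga_stop(sprintf("tree address(es) claimed by several descriptors: %s",
                       paste(dup[conflicting], collapse = ", ")),
               "dga_data_error")
    }
  }
  nodes <- unique(desc)
  parents <- stats::setNames(vector("list", length(nodes)), nodes)
  addresses <- stats::setNames(split(addr, factor(desc, levels = nodes)), nodes)
  synthetic <- character()
  orphaned <- character()
  for (i in seq_along(addr)) {
    a <- addr[i]
    segs <- strsplit(a, ".", fixed = TRUE)[[1L]]
    if (length(segs) == 1L) next  # top-level address: a root
    parent_addr <- paste(segs[-length(segs)], collapse = ".")
    child <- desc[i]
    if (parent_addr %in% names(addr_to_desc)) {
      p <- addr_to_desc[[parent_addr]]
      if (!identical(p, child)) parents[[child]] <- union(parents[[child]], p)
    } else {
      root_id <- paste0("synthetic:", segs[1L])
      if (!root_id %in% synthetic) {
        synthetic <- c(synthetic, root_id)
        parents[[root_id]] <- character()
        addresses[[root_id]] <- character()
      }
      parents[[child]] <- union(parents[[child]], root_id)
      orphaned <- c(orphaned, a)
    }
  }
  if (length(orphaned) > 0L) {
    warning(sprintf("%d address(es) with no parent descriptor attached to synthetic category root(s): %s",
                    length(orphaned), paste(utils::head(orphaned, 5L), collapse = ", ")))
  }
  ontology_dag(parents, addresses, synthetic)
}

#' @rdname write_cgi
#' @export
write_mesh_tree <- function(x, path) {
  stopifnot(is_ontology_dag(x))
  ids <- rep(names(x$addresses), lengths(x$addresses))
  write_table_tsv(data.frame(DescriptorID = ids,
                             TreeAddress = unlist(x$addresses, use.names = FALSE) %||% character()),
                  path)
}
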