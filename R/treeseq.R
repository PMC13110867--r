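#' Export a genealogy as tree-sequence tables
#'
#' Converts a consistent genealogy into node/edge/site/mutation tables in
#' the tree-sequence (tskit) layout: 0-based node ids, times in
#' generations (latitudes scaled by `2 Ne`), one edge row per maximal
#' ancestral interval, sites at the marker positions with ancestral state
#' `"0"`, and the unique mutation edge per marker reported through its
#' child node. Edges are sorted by parent time, parent, child and left
#' endpoint as the tree-sequence ordering requirements demand.
#'
#' @param g a consistent genealogy (`validate_genealogy(g)$consistent`).
#' @return A list of data frames `nodes`, `edges`, `sites`, `mutations`.
#' @export
as_tree_tables <- function(g) {
  cons <- is_consistent(g)
  if (!cons)
    stop("refusing to export an inconsistent genealogy: ",
         "one mutation per site is the export contract")
  scale <- 2 * g$sample$Ne
  nodes <- data.frame(
    id = seq_along(g$lat) - 1L,
    is_sample = as.integer(g$kind == KIND_LEAF),
    time = g$lat * scale)
  rows <- list()
  for (e in active_edges(g)) {
    anc <- unclass(g$e_anc[[e]])
    if (length(anc) == 0L) next
    a <- anc[c(TRUE, FALSE)]; b <- anc[c(FALSE, TRUE)]
    rows[[length(rows) + 1L]] <- data.frame(
      left = a, right = pmin(b, g$sample$seq_length),
      parent = g$e_parent[e] - 1L, child = g$e_child[e] - 1L)
  }
  edges <- do.call(rbind, rows)
  edges <- edges[order(nodes$time[edges$parent + 1L], edges$parent,
                       edges$child, edges$left), , drop = FALSE]
  rownames(edges) <- NULL
  sites <- data.frame(id = seq_len(g$sample$s) - 1L,
                      position = g$sample$positions,
                      ancestral_state = "0")
  counts <- attr(cons, "mutation_counts")
  mut_site <- which(counts == 1L)
  mut_node <- vapply(mut_site, function(k) {
    e <- count_mutations_at(g, k)[1L]
    g$e_child[e] - 1L
  }, integer(1))
  mutations <- data.frame(site = mut_site - 1L, node = mut_node,
                          derived_state = "1")
  list(nodes = nodes, edges = edges, sites = sites, mutations = mutations,
       sequence_length = g$sample$seq_length)
}

#' Write/read tree-sequence tables as text
#'
#' The text layout matches what `tskit.load_text` consumes: one
#' tab-delimited file per table with standard column headers, plus a
#' small JSON metadata file recording the run configuration.
#'
#' @param tables output of [as_tree_tables()].
#' @param dir output directory (created if needed).
#' @param meta optional named list serialized to `meta.json`.
#' @return `dir`, invisibly.
#' @export
write_tree_tables <- function(tables, dir, meta = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)
  writeLines(c("is_sample\ttime",
               paste(tables$nodes$is_sample, fmt(tables$nodes$time), sep = "\t")),
             file.path(dir, "nodes.txt"))
  writeLines(c("left\tright\tparent\tchild",
               paste(fmt(tables$edges$left), fmt(tables$edges$right),
                     tables$edges$parent, tables$edges$child, sep = "\t")),
             file.path(dir, "edges.txt"))
  writeLines(c("position\tancestral_state",
               paste(fmt(tables$sites$position), tables$sites$ancestral_state,
                     sep = "\t")),
             file.path(dir, "sites.txt"))
  writeLines(c("site\tnode\tderived_state",
               paste(tables$mutations$site, tables$mutations$node,
                     tables$mutations$derived_state, sep = "\t")),
             file.path(dir, "mutations.txt"))
  if (!is.null(meta))
    jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(dir)
}

#' @rdname write_tree_tables
#' @export
read_tree_tables <- function(dir) {
  nodes <- utils::read.table(file.path(dir, "nodes.txt"), header = TRUE,
                             sep = "\t")
  nodes$id <- seq_len(nrow(nodes)) - 1L
  list(nodes = nodes,
       edges = utils::read.table(file.path(dir, "edges.txt"), header = TRUE,
                                 sep = "\t"),
       sites = utils::read.table(file.path(dir, "sites.txt"), header = TRUE,
                                 sep = "\t", colClasses = c("numeric", "character")),
       mutations = utils::read.table(file.path(dir, "mutations.txt"),
                                     header = TRUE, sep = "\t",
                                     colClasses = c("integer", "integer", "character")))
}

#' Decode sample genotypes from tree-sequence tables
#'
#' Reconstructs the 0/1 genotype matrix encoded by the tables: for each
#' site, the sample nodes reachable downward from the mutation's node
#' through edges covering the site's position carry the derived state.
#' Used as the export/import round-trip oracle.
#'
#' @param tables a table list from [as_tree_tables()] or
#'   [read_tree_tables()].
#' @return An `n x s` integer matrix, haplotypes in node id order.
#' @export
decode_tree_genotypes <- function(tables) {
  samples <- tables$nodes$id[tables$nodes$is_sample == 1L]
  s <- nrow(tables$sites)
  out <- matrix(0L, nrow = length(samples), ncol = s)
  rank <- match(samples, tables$nodes$id)
  for (j in seq_len(s)) {
    mu <- tables$mutations[tables$mutations$site == j - 1L, , drop = FALSE]
    if (nrow(mu) == 0L) next
    p <- tables$sites$position[j]
    sel <- tables$edges$left <= p & tables$edges$right > p
    for (i in seq_len(nrow(mu))) {
      stack <- mu$node[i]
      while (length(stack) > 0L) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        hit <- match(v, samples)
        if (!is.na(hit)) out[rank[hit], j] <- 1L
        stack <- c(stack, tables$edges$child[sel & tables$edges$parent == v])
      }
    }
  }
  out
}
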