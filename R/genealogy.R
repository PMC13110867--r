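#' Genealogy objects
#'
#' Coalescent trees and ancestral recombination graphs share one mutable
#' representation (an environment, so that event surgery does not copy the
#' graph): vertices carry a latitude (time-depth from the sample in
#' coalescent units, leaves at 0), a haplotype and a kind (leaf,
#' coalescence or recombination); edges carry the interval set of genomic
#' material ancestral to the sample that flows through them. A
#' recombination vertex has one child edge and two parental edges and is
#' associated with a recombination mask: a partition `{left, right}` of
#' `[0, Inf)` deciding which material flows to each parent. A coalescence
#' vertex has two child edges and (except for the root) one parental edge.
#'
#' The interval rule links the two layers: a parental edge's ancestral set
#' equals the intersection of its recombination mask (taken as `[0, Inf)`
#' for coalescence vertices) with the union of the child edges' ancestral
#' sets. Restricting the graph to edges ancestral for a position `p` and
#' contracting pass-through vertices yields the marginal tree at `p`.
#'
#' @name genealogy
#' @keywords internal
NULL

KIND_LEAF <- 0L
KIND_COAL <- 1L
KIND_RECOMB <- 2L

# Fresh genealogy holding only the sample's leaves.
g_new <- function(sample) {
  g <- new.env(parent = emptyenv())
  n <- sample$n
  g$sample <- sample
  g$lat <- rep(0, n)
  g$kind <- rep(KIND_LEAF, n)
  g$hap <- sample$haplotypes
  g$e_child <- integer(0)
  g$e_parent <- integer(0)
  g$e_anc <- list()
  g$e_side <- integer(0)           # 0 plain, 1/2 = left/right parental edge
  g$e_active <- logical(0)
  g$up <- rep(list(integer(0)), n)    # edges with this vertex as child
  g$down <- rep(list(integer(0)), n)  # edges with this vertex as parent
  g$mask_left <- vector("list", n)
  g$mask_right <- vector("list", n)
  g$root <- NA_integer_
  g$n_recomb <- 0L
  g$logdens <- 0
  g$hashkey <- integer(0)
  g$seed <- NA_integer_
  class(g) <- c("genealogy")
  g
}

g_add_vertex <- function(g, lat, kind, hap) {
  id <- length(g$lat) + 1L
  g$lat[id] <- lat
  g$kind[id] <- kind
  g$hap[[id]] <- hap
  g$up[[id]] <- integer(0)
  g$down[[id]] <- integer(0)
  g$mask_left[id] <- list(NULL)
  g$mask_right[id] <- list(NULL)
  id
}

g_add_edge <- function(g, child, parent, anc, side = 0L) {
  e <- length(g$e_child) + 1L
  g$e_child[e] <- child
  g$e_parent[e] <- parent
  g$e_anc[[e]] <- anc
  g$e_side[e] <- side
  g$e_active[e] <- TRUE
  g$up[[child]] <- c(g$up[[child]], e)
  g$down[[parent]] <- c(g$down[[parent]], e)
  e
}

g_del_edge <- function(g, e) {
  stopifnot(g$e_active[e])
  g$e_active[e] <- FALSE
  ch <- g$e_child[e]; pa <- g$e_parent[e]
  g$up[[ch]] <- setdiff(g$up[[ch]], e)
  g$down[[pa]] <- setdiff(g$down[[pa]], e)
  invisible(g)
}

active_edges <- function(g) which(g$e_active)

edge_span <- function(g, e) g$lat[g$e_parent[e]] - g$lat[g$e_child[e]]

# mask applied to a parental edge by its child vertex
edge_side_mask <- function(g, e) {
  v <- g$e_child[e]
  if (g$kind[v] != KIND_RECOMB) return(iset_raw(c(0, Inf)))
  if (g$e_side[e] == 1L) g$mask_left[[v]]
  else if (g$e_side[e] == 2L) g$mask_right[[v]]
  else stop("parental edge of a recombination vertex lacks a side")
}

.bitpow <- as.integer(2^(0:7))

# state of marker k (1-based) on vertex v's haplotype
vertex_bit <- function(g, v, k) {
  h <- unclass(g$hap[[v]])
  (as.integer(h[(k - 1L) %/% 8L + 1L]) %/% .bitpow[(k - 1L) %% 8L + 1L]) %% 2L
}

# shallow structural copy; vectors/lists are copy-on-write so this is cheap
g_copy <- function(g) {
  g2 <- new.env(parent = emptyenv())
  for (nm in ls(g, all.names = TRUE))
    assign(nm, get(nm, envir = g), envir = g2)
  class(g2) <- class(g)
  g2
}

# union of ancestral sets of the child edges of v
child_union <- function(g, v) {
  es <- g$down[[v]]
  if (length(es) == 0L) return(iset_raw(c(0, g$sample$seq_length)))
  out <- g$e_anc[[es[1L]]]
  for (e in es[-1L]) out <- iset_union(out, g$e_anc[[e]])
  out
}

# recompute v's haplotype from its children under the GF(2) AND rule,
# masking each child's contribution by the child edge's ancestral set
recompute_hap <- function(g, v) {
  if (g$kind[v] == KIND_LEAF) return(g$hap[[v]])
  es <- g$down[[v]]
  if (g$kind[v] == KIND_RECOMB) return(g$hap[[g$e_child[es[1L]]]])
  s <- g$sample$s
  acc <- pad_mask(s)                       # all ones over live markers
  pos <- g$sample$positions
  for (e in es) {
    m <- unclass(interval_mask(pos, g$e_anc[[e]]))
    hc <- unclass(g$hap[[g$e_child[e]]])
    acc <- acc & (hc | !m)
  }
  new_bitseq_raw(acc & pad_mask(s), s)
}

recompute_edge_anc <- function(g, e) {
  iset_intersect(edge_side_mask(g, e), child_union(g, g$e_child[e]))
}

#' Marginal edges and marginal tree
#'
#' `marginal_edges` lists the edges whose ancestral interval set contains
#' `p`. `marginal_tree` contracts the induced subgraph through pass-through
#' vertices (recombination vertices and single-marginal-child
#' coalescences) into the binary tree over the sample that the ARG encodes
#' at position `p`.
#'
#' @param g a genealogy.
#' @param p a position in `[0, seq_length)`.
#' @return For `marginal_tree`, a list with elements `root`, `cvert`
#'   (contracted vertex ids), `cparent` (named by vertex), `cchildren`,
#'   `chain` (ARG edge ids composing each contracted edge, named by child
#'   vertex) and `medge` (all marginal ARG edge ids).
#' @export
marginal_edges <- function(g, p) {
  if (p < 0 || p >= g$sample$seq_length) stop("position outside [0, seq_length)")
  es <- active_edges(g)
  es[vapply(es, function(e) iset_contains(g$e_anc[[e]], p), logical(1))]
}

#' @rdname marginal_edges
#' @export
marginal_tree <- function(g, p) {
  medge <- marginal_edges(g, p)
  mparent <- rep(NA_integer_, length(g$lat))   # marginal parent edge per vertex
  nchild <- integer(length(g$lat))
  for (e in medge) {
    mparent[g$e_child[e]] <- e
    nchild[g$e_parent[e]] <- nchild[g$e_parent[e]] + 1L
  }
  leaves <- which(g$kind == KIND_LEAF)
  cvert <- sort(unique(c(leaves, which(nchild >= 2L))))
  incv <- logical(length(g$lat)); incv[cvert] <- TRUE
  cparent <- rep(NA_integer_, length(g$lat))
  chain <- vector("list", length(g$lat))
  for (v in cvert) {
    e <- mparent[v]
    path <- integer(0)
    while (!is.na(e)) {
      path <- c(path, e)
      u <- g$e_parent[e]
      if (incv[u]) { cparent[v] <- u; break }
      e <- mparent[u]
    }
    chain[[v]] <- if (is.na(cparent[v])) integer(0) else path
  }
  root <- cvert[is.na(cparent[cvert])]
  cchildren <- split(cvert[!is.na(cparent[cvert])],
                     factor(cparent[cvert[!is.na(cparent[cvert])]], levels = cvert))
  list(root = root, cvert = cvert, cparent = cparent, cchildren = cchildren,
       chain = chain, medge = medge, mparent = mparent, nchild = nchild)
}

#' Convert a marginal tree to an ape phylogeny
#'
#' @param g a genealogy.
#' @param p position of the marginal tree.
#' @return An [ape::as.phylo] object with branch lengths in coalescent
#'   units.
#' @export
marginal_phylo <- function(g, p) {
  mt <- marginal_tree(g, p)
  leaves <- which(g$kind == KIND_LEAF)
  if (length(mt$root) != 1L) stop("marginal tree at p = ", p, " has no unique root")
  n <- length(leaves)
  # ape numbering: tips 1..n, internals n+1.. in preorder (root = n+1),
  # edges emitted cladewise
  idx <- integer(length(g$lat))
  idx[leaves] <- seq_len(n)
  nint <- 0L
  ep <- integer(0); ec <- integer(0); elen <- numeric(0)
  visit <- function(v) {
    kids <- mt$cchildren[[as.character(v)]]
    if (is.null(kids) || length(kids) == 0L) return(invisible())
    nint <<- nint + 1L
    idx[v] <<- n + nint
    for (k in kids) {
      if (is.null(mt$cchildren[[as.character(k)]]) ||
          length(mt$cchildren[[as.character(k)]]) == 0L) {
        ep <<- c(ep, idx[v]); ec <<- c(ec, idx[k])
        elen <<- c(elen, g$lat[v] - g$lat[k])
      } else {
        here <- length(ep) + 1L
        ep <<- c(ep, idx[v]); ec <<- c(ec, NA_integer_)
        elen <<- c(elen, NA_real_)
        visit(k)
        ec[here] <<- idx[k]
        elen[here] <<- g$lat[v] - g$lat[k]
      }
    }
  }
  visit(mt$root)
  phy <- list(edge = cbind(ep, ec, deparse.level = 0L), edge.length = elen,
              tip.label = g$sample$names[seq_len(n)],
              Nnode = nint)
  class(phy) <- "phylo"
  phy
}

# pairwise coalescence latitudes at position p (n x n symmetric matrix)
pairwise_tmrca <- function(g, p) {
  mt <- marginal_tree(g, p)
  n <- g$sample$n
  tm <- matrix(0, n, n)
  below <- function(v) {
    kids <- mt$cchildren[[as.character(v)]]
    if (is.null(kids) || length(kids) == 0L) return(v)
    sets <- lapply(kids, below)
    if (length(sets) >= 2L) {
      for (i in seq_len(length(sets) - 1L)) for (j in (i + 1L):length(sets)) {
        tm[sets[[i]], sets[[j]]] <<- g$lat[v]
        tm[sets[[j]], sets[[i]]] <<- g$lat[v]
      }
    }
    unlist(sets)
  }
  below(mt$root)
  tm
}

# distinct interval endpoints of the active edges, clipped to [0, l]
segment_breaks <- function(g) {
  l <- g$sample$seq_length
  pts <- unlist(lapply(active_edges(g), function(e) unclass(g$e_anc[[e]])))
  pts <- sort(unique(c(0, l, pts[is.finite(pts) & pts > 0 & pts < l])))
  pts
}

#' Genealogy summary statistics
#'
#' `n_recombinations` counts recombination vertices. `tree_height` is the
#' latitude of the grand MRCA. `diversity` is the branch-length diversity:
#' the average over leaf pairs of twice their marginal coalescence time,
#' integrated uniformly over `[0, seq_length)` (segments between
#' recombination breakpoints are weighted by their physical length).
#'
#' @param g a genealogy.
#' @return A list with elements `n_recombinations`, `tree_height`,
#'   `diversity`.
#' @export
genealogy_stats <- function(g) {
  n <- g$sample$n
  l <- g$sample$seq_length
  br <- segment_breaks(g)
  div <- 0
  for (i in seq_len(length(br) - 1L)) {
    mid <- (br[i] + br[i + 1L]) / 2
    tm <- pairwise_tmrca(g, mid)
    div <- div + (br[i + 1L] - br[i]) / l * mean(2 * tm[upper.tri(tm)])
  }
  list(n_recombinations = sum(g$kind == KIND_RECOMB),
       tree_height = g$lat[g$root],
       diversity = div)
}

# naive per-marker mutation edge recount: the independent reference used by
# validate() and by tests against the chunked scanner
count_mutations_at <- function(g, k) {
  p <- g$sample$positions[k]
  es <- marginal_edges(g, p)
  hits <- es[vapply(es, function(e) {
    vertex_bit(g, g$e_child[e], k) != vertex_bit(g, g$e_parent[e], k)
  }, logical(1))]
  sort(hits)
}

#' Validate a genealogy
#'
#' Checks structural invariants (vertex degrees by kind, positive edge
#' spans, leaf latitudes at zero, the interval rule at every vertex, the
#' haplotype AND rule, a unique root, the recombination/coalescence vertex
#' count identity, and that every marker position induces a binary marginal
#' tree over the full sample) and infinite-sites consistency (at most one
#' mutation edge per marker, recounted naively). Structural violations are
#' reported separately from inconsistency.
#'
#' @param g a genealogy.
#' @param grid additionally check the marginal-tree property on this many
#'   evenly spaced positions (0 disables).
#' @return A list with `ok`, `structural_ok`, `consistent`,
#'   `mutation_counts` (one count per marker) and `messages`.
#' @export
validate_genealogy <- function(g, grid = 0L) {
  msg <- character(0)
  n <- g$sample$n
  # degrees
  for (v in seq_along(g$lat)) {
    nup <- length(g$up[[v]]); ndown <- length(g$down[[v]])
    ok <- switch(as.character(g$kind[v]),
      "0" = ndown == 0L && nup == 1L,
      "1" = ndown == 2L && nup <= 1L,
      "2" = ndown == 1L && nup == 2L)
    if (!isTRUE(ok))
      msg <- c(msg, sprintf("vertex %d (kind %d) has degree down=%d up=%d",
                            v, g$kind[v], ndown, nup))
    if (g$kind[v] == KIND_LEAF && g$lat[v] != 0)
      msg <- c(msg, sprintf("leaf %d has nonzero latitude", v))
    if (g$kind[v] == KIND_RECOMB) {
      ml <- g$mask_left[[v]]; mr <- g$mask_right[[v]]
      if (is.null(ml) || is.null(mr)) {
        msg <- c(msg, sprintf("recombination vertex %d lacks a mask", v))
      } else {
        if (!identical(unclass(iset_union(ml, mr)), c(0, Inf)))
          msg <- c(msg, sprintf("mask of vertex %d does not cover [0, Inf)", v))
        if (!iset_is_empty(iset_intersect(ml, mr)))
          msg <- c(msg, sprintf("mask of vertex %d overlaps itself", v))
      }
    }
  }
  roots <- which(vapply(seq_along(g$lat), function(v) length(g$up[[v]]) == 0L,
                        logical(1)))
  if (length(roots) != 1L || roots[1L] != g$root)
    msg <- c(msg, "root is not unique or mismatches the stored root")
  if (sum(g$kind == KIND_COAL) != sum(g$kind == KIND_RECOMB) + n - 1L)
    msg <- c(msg, "#coalescence != #recombination + n - 1")
  for (e in active_edges(g)) {
    if (edge_span(g, e) <= 0)
      msg <- c(msg, sprintf("edge %d has nonpositive span", e))
    if (!identical(unclass(g$e_anc[[e]]), unclass(recompute_edge_anc(g, e))))
      msg <- c(msg, sprintf("edge %d violates the interval rule", e))
  }
  for (v in which(g$kind != KIND_LEAF)) {
    if (!identical(unclass(g$hap[[v]]), unclass(recompute_hap(g, v))))
      msg <- c(msg, sprintf("vertex %d violates the haplotype AND rule", v))
  }
  # marginal-tree property at marker positions (+ optional grid)
  pts <- g$sample$positions
  if (grid > 0L)
    pts <- sort(unique(c(pts, seq(0, g$sample$seq_length,
                                  length.out = grid + 1L)[-(grid + 1L)])))
  for (p in pts) {
    mt <- tryCatch(marginal_tree(g, p), error = function(e) NULL)
    bad <- is.null(mt) || length(mt$root) != 1L ||
      !all(which(g$kind == KIND_LEAF) %in% mt$cvert) ||
      any(vapply(setdiff(mt$cvert, c(which(g$kind == KIND_LEAF))), function(v) {
        kids <- mt$cchildren[[as.character(v)]]
        length(kids) != 2L
      }, logical(1)))
    if (bad) msg <- c(msg, sprintf("marginal tree at p = %g is not binary over the sample", p))
  }
  structural_ok <- length(msg) == 0L
  counts <- vapply(seq_len(g$sample$s),
                   function(k) length(count_mutations_at(g, k)), integer(1))
  consistent <- all(counts <= 1L)
  list(ok = structural_ok && consistent,
       structural_ok = structural_ok,
       consistent = consistent,
       mutation_counts = counts,
       messages = msg)
}

#' @rdname validate_genealogy
#' @export
is_consistent <- function(g) {
  counts <- vapply(seq_len(g$sample$s),
                   function(k) length(count_mutations_at(g, k)), integer(1))
  structure(all(counts <= 1L), mutation_counts = counts)
}

#' @export
print.genealogy <- function(x, ...) {
  kind <- if (x$n_recomb > 0L) "ancestral recombination graph" else "coalescent tree"
  cat("<", paste(class(x), collapse = "/"), "> ", kind, "\n", sep = "")
  cat("  sample: n = ", x$sample$n, ", s = ", x$sample$s, " markers\n", sep = "")
  cat("  recombinations: ", x$n_recomb,
      ", TgMRCA = ", signif(x$lat[x$root], 5), " (coalescent units)\n", sep = "")
  invisible(x)
}

#' @export
summary.genealogy <- function(object, ...) {
  st <- genealogy_stats(object)
  cons <- is_consistent(object)
  out <- c(st, list(consistent = as.logical(cons),
                    max_mutations = max(attr(cons, "mutation_counts")),
                    n = object$sample$n, s = object$sample$s,
                    log_density = object$logdens))
  class(out) <- "summary.genealogy"
  out
}

#' @export
print.summary.genealogy <- function(x, ...) {
  cat("Genealogy over n =", x$n, "haplotypes,", x$s, "markers\n")
  cat("  recombination vertices:", x$n_recombinations, "\n")
  cat("  TgMRCA:", signif(x$tree_height, 5), "coalescent units\n")
  cat("  branch-length diversity:", signif(x$diversity, 5), "\n")
  cat("  ISM-consistent:", x$consistent,
      sprintf("(max mutations/marker: %d)\n", x$max_mutations))
  cat("  accumulated log-density of the initial tree:", signif(x$log_density, 6), "\n")
  invisible(x)
}

#' @export
plot.genealogy <- function(x, p = NULL, ...) {
  if (is.null(p)) p <- x$sample$positions[1L]
  phy <- marginal_phylo(x, p)
  ape::plot.phylo(phy, ...)
  graphics::mtext(sprintf("marginal tree at %.6g bp", p), side = 3, line = 0.2,
                  cex = 0.8)
  invisible(phy)
}
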