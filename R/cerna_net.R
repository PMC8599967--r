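#' Canonical miRNA seed matching
#'
#' Scans a target sequence for canonical seed sites of a miRNA
#' (TargetScan-style site classes). With the miRNA written 5'->3', the
#' target is searched for the reverse complement of miRNA positions 2-8
#' (7mer-m8); a site is promoted to 8mer when the target base immediately
#' 3' of the match (opposite miRNA position 1) is an A; a 7mer-A1 site
#' matches positions 2-7 with an A opposite position 1. U and T are
#' equivalent; windows containing other characters never match.
#'
#' @param mirna miRNA sequence, 5'->3', length >= 8 (RNA or DNA alphabet).
#' @param target target sequence (RNA or DNA alphabet).
#' @return data.frame with \code{position} (1-based start of the seed-match
#'   window in the target) and \code{type} (8mer, 7mer-m8, 7mer-A1);
#'   zero rows when no site exists.
#' @export
seed_match <- function(mirna, target) {
  if (nchar(mirna) < 8L) stop("miRNA must be at least 8 nt long")
  empty <- data.frame(position = integer(), type = character())
  if (is.na(target) || nchar(target) < 7L) return(empty)
  mir <- toupper(chartr("Uu", "Tt", mirna))
  tgt <- toupper(chartr("Uu", "Tt", target))

  m8site <- revcomp(substr(mir, 2L, 8L))                 # 7 nt
  a1site <- paste0(revcomp(substr(mir, 2L, 7L)), "A")    # 7 nt
  n <- nchar(tgt)
  win <- substring(tgt, 1:(n - 6L), 7:n)

  pos_m8 <- which(win == m8site)
  pos_a1 <- which(win == a1site)
  out <- list()
  if (length(pos_m8)) {
    after <- ifelse(pos_m8 + 7L <= n, substr(rep(tgt, length(pos_m8)),
                                             pos_m8 + 7L, pos_m8 + 7L), "")
    out[[1L]] <- data.frame(
      position = pos_m8,
      type = ifelse(after == "A", "8mer", "7mer-m8"),
      stringsAsFactors = FALSE
    )
  }
  # a 7mer-A1 window one base right of an m8 match is part of that site
  pos_a1 <- pos_a1[!(pos_a1 - 1L) %in% pos_m8]
  if (length(pos_a1)) {
    out[[length(out) + 1L]] <- data.frame(
      position = pos_a1, type = "7mer-A1", stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$position), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assemble a lncRNA/circRNA - miRNA - mRNA (ceRNA) network
#'
#' An edge connects a lncRNA/circRNA to a miRNA when the miRNA has at least
#' one seed site on the lnc/circ sequence, and a miRNA to an mRNA when it
#' has at least one site on the mRNA 3'UTR. Duplicate sites on one pair
#' collapse into a single edge with a site count.
#'
#' @param lnc_circ_seqs named character vector of lncRNA/circRNA sequences.
#' @param mirna_seqs named character vector of miRNA sequences (5'->3').
#' @param mrna_utr_seqs named character vector of mRNA 3'UTR sequences.
#' @return list with \code{edges} (data.frame source, target, tier, n_sites)
#'   and \code{nodes} (data.frame id, tier).
#' @export
build_cerna <- function(lnc_circ_seqs, mirna_seqs, mrna_utr_seqs) {
  pair_edges <- function(mirs, targets, tier) {
    rows <- list()
    for (mn in names(mirs)) {
      for (tn in names(targets)) {
        sites <- seed_match(mirs[[mn]], targets[[tn]])
        if (nrow(sites) > 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            source = if (tier == "lnc_mir") tn else mn,
            target = if (tier == "lnc_mir") mn else tn,
            tier = tier, n_sites = nrow(sites),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(source = character(), target = character(),
                 tier = character(), n_sites = integer())
  }
  edges <- rbind(
    pair_edges(mirna_seqs, lnc_circ_seqs, "lnc_mir"),
    pair_edges(mirna_seqs, mrna_utr_seqs, "mir_mrna")
  )
  node_df <- function(x, tier) {
    ids <- as.character(names(x) %||% character(0))
    data.frame(id = ids, tier = rep(tier, length(ids)),
               stringsAsFactors = FALSE)
  }
  nodes <- rbind(node_df(lnc_circ_seqs, "lnc_circ"),
                 node_df(mirna_seqs, "mirna"),
                 node_df(mrna_utr_seqs, "mrna"))
  rownames(edges) <- rownames(nodes) <- NULL
  list(edges = edges, nodes = nodes)
}

# Density of an undirected simple graph (1 for graphs of one vertex).
graph_density <- function(g) {
  nv <- igraph::vcount(g)
  if (nv < 2L) return(0)
  2 * igraph::ecount(g) / (nv * (nv - 1))
}

# MCODE vertex weight: highest k-core of the closed neighborhood times the
# density of that core.
mcode_weights <- function(g) {
  vs <- igraph::V(g)
  w <- numeric(length(vs))
  for (i in seq_along(vs)) {
    nb <- c(i, as.integer(igraph::neighbors(g, i)))
    sub <- igraph::induced_subgraph(g, unique(nb))
    if (igraph::ecount(sub) == 0L) next
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_sub <- igraph::induced_subgraph(sub, which(core >= kmax))
    w[i] <- kmax * graph_density(core_sub)
  }
  stats::setNames(w, igraph::V(g)$name)
}

#' MCODE-style clustering of an interaction graph
#'
#' Molecular-complex detection: (1) every vertex is weighted by the highest
#' k-core of its closed neighborhood times the density of that core; (2)
#' complexes are seeded from the highest-weighted unassigned vertex and
#' grown outward, including neighbors whose weight is at least
#' \code{(1 - node_score_cutoff)} times the seed weight; (3) with
#' \code{haircut} the grown complex is iteratively stripped of vertices
#' with fewer than two connections inside it. Complexes smaller than
#' \code{min_size} are dropped. Ties are broken by vertex name, so the
#' output is deterministic and invariant to edge-list permutation.
#'
#' @param edges two-column data.frame (or matrix) of undirected edges, or an
#'   igraph object. Self-loops and duplicate edges are removed.
#' @param node_score_cutoff inclusion threshold as a fraction of the seed
#'   weight (default 0.2).
#' @param haircut remove singly-connected vertices from complexes
#'   (default TRUE, mirroring the usual defaults).
#' @param fluff reserved; only FALSE is supported.
#' @param min_size minimum complex size (default 3).
#' @return list of clusters, each a list with \code{members} (sorted vertex
#'   names), \code{score} (density times size) and \code{density}; ordered
#'   by decreasing score.
#' @export
mcode_cluster <- function(edges, node_score_cutoff = 0.2, haircut = TRUE,
                          fluff = FALSE, min_size = 3L) {
  if (!identical(fluff, FALSE)) stop("fluff expansion is not implemented")
  g <- if (inherits(edges, "igraph")) edges else {
    em <- as.matrix(edges[, 1:2, drop = FALSE])
    if (nrow(em) == 0L) return(list())
    igraph::graph_from_edgelist(matrix(as.character(em), ncol = 2),
                                directed = FALSE)
  }
  g <- igraph::simplify(g)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g <- igraph::permute(g, order(order(igraph::V(g)$name)))  # stable order
  nv <- igraph::vcount(g)
  if (nv == 0L) return(list())

  w <- mcode_weights(g)
  assigned <- rep(FALSE, nv)
  seed_order <- order(-w, igraph::V(g)$name)
  clusters <- list()

  for (s in seed_order) {
    if (assigned[s] || w[s] <= 0) next
    thr <- (1 - node_score_cutoff) * w[s]
    members <- s
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(igraph::neighbors(g, v))) {
          if (!assigned[u] && !(u %in% members) && w[u] >= thr) {
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- sort(unique(nxt))
    }
    members <- sort(members)   # align with induced_subgraph vertex order
    if (haircut) {
      repeat {
        sub <- igraph::induced_subgraph(g, members)
        deg <- igraph::degree(sub)
        if (all(deg >= 2) || length(members) == 0L) break
        members <- members[deg >= 2]
      }
    }
    if (length(members) >= min_size) {
      sub <- igraph::induced_subgraph(g, members)
      dens <- graph_density(sub)
      clusters[[length(clusters) + 1L]] <- list(
        members = sort(igraph::V(g)$name[members]),
        score = dens * length(members),
        density = dens
      )
      assigned[members] <- TRUE
    }
  }
  if (length(clusters) > 1L) {
    ord <- order(-vapply(clusters, `[[`, numeric(1), "score"),
                 vapply(clusters, function(cl) cl$members[1], character(1)))
    clusters <- clusters[ord]
  }
  clusters
}
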