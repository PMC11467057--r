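# Clustering families into candidate clans
#
# Families become nodes of an undirected graph with an edge wherever the
# final pair score strictly exceeds a threshold (the operating point is
# normally chosen from the sensitivity curve, e.g. the score at 1%
# conservative FDR). Leiden community detection then yields clusters that
# are compared with the existing clan annotation: clusters dominated by one
# clan but containing clanless members suggest new clan members, clusters
# mixing clans suggest clan merges, and all-clanless clusters suggest new
# clans.

#' Build the thresholded family similarity graph
#'
#' @param scores a `final_scores` object
#' @param threshold strict lower bound on edge scores
#' @return an igraph undirected graph over all families (isolated nodes
#'   kept), edge attribute `weight` = final score
#' @export
build_graph <- function(scores, threshold) {
  if (!is.finite(threshold)) {
    # -Inf is allowed (complete graph); NA/NaN are not
    if (is.na(threshold)) famsim_stop("invalid_config", "threshold must not be NA")
  }
  ps <- pair_scores(scores)
  keep <- !is.na(ps$score) & ps$score > threshold
  edges <- ps[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("fam_i", "fam_j")], directed = FALSE,
    vertices = data.frame(name = sort(rownames(scores$matrix))))
  igraph::E(g)$weight <- edges$score
  g
}

#' Leiden community detection on the family graph
#'
#' Delegated to igraph's Leiden implementation with the modularity
#' objective. The seed is mandatory: given the same seed and library
#' version, the assignment is reproducible.
#'
#' @param graph graph from [build_graph()]
#' @param resolution resolution parameter (default 1.0)
#' @param seed integer RNG seed
#' @param weighted use edge weights (default TRUE)
#' @param n_iterations Leiden refinement iterations (default 5)
#' @return named integer vector: family -> cluster id; isolated nodes get
#'   their own singleton clusters
#' @export
leiden_clusters <- function(graph, resolution = 1.0, seed,
                            weighted = TRUE, n_iterations = 5L) {
  if (missing(seed)) famsim_stop("invalid_config", "a seed is required")
  if (igraph::vcount(graph) == 0L) {
    famsim_stop("empty_graph", "graph has no vertices")
  }
  w <- if (weighted && igraph::ecount(graph) > 0L) igraph::E(graph)$weight
       else NULL
  set.seed(as.integer(seed))
  comm <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                 resolution = resolution, weights = w,
                                 n_iterations = n_iterations)
  m <- igraph::membership(comm)
  stats::setNames(as.integer(m), names(m))
}

#' Cluster-vs-clan concordance report
#'
#' For every non-singleton cluster: clan composition of its members, the
#' dominant clan and its purity among clan-labeled members, and three flags:
#' * `new_member_candidates`: clanless members of a cluster whose labeled
#'   members are majority one clan — candidates for joining it;
#' * `merge_candidate`: cluster contains members of two or more clans;
#' * `new_clan_candidate`: all members clanless.
#' Isolated (singleton) families are listed separately.
#'
#' @param assignment named vector from [leiden_clusters()]
#' @param cm a `clan_map`
#' @param purity_threshold dominant-clan fraction required to flag clanless
#'   members as new-member candidates (default 0.5, strict)
#' @return list(clusters = list of per-cluster reports, singletons =
#'   character vector)
#' @export
cluster_clan_report <- function(assignment, cm, purity_threshold = 0.5) {
  ids <- split(names(assignment), assignment)
  sizes <- lengths(ids)
  singles <- unlist(ids[sizes == 1L], use.names = FALSE)
  clusters <- lapply(ids[sizes > 1L], function(members) {
    clans <- clan_of(cm, members)
    labeled <- clans[!is.na(clans)]
    hist <- if (length(labeled)) sort(table(labeled), decreasing = TRUE)
            else table(character(0))
    dominant <- if (length(hist)) names(hist)[1L] else NA_character_
    purity <- if (length(labeled)) as.integer(hist[1L]) / length(labeled)
              else NA_real_
    clanless <- members[is.na(clans)]
    list(members = members,
         clan_histogram = hist,
         dominant_clan = dominant,
         purity = purity,
         new_member_candidates =
           if (length(clanless) && !is.na(purity) && purity > purity_threshold)
             clanless else character(0),
         merge_candidate = length(hist) >= 2L,
         new_clan_candidate = length(labeled) == 0L)
  })
  list(clusters = clusters, singletons = sort(singles))
}

#' Flatten a cluster report into a per-family table
#'
#' @param report output of [cluster_clan_report()]
#' @param assignment the assignment the report came from
#' @return data.frame family, cluster, clan, dominant_clan, flag
#' @export
cluster_report_table <- function(report, assignment) {
  rows <- lapply(names(report$clusters), function(cid) {
    cl <- report$clusters[[cid]]
    flag <- if (cl$new_clan_candidate) "new_clan_candidate"
            else if (cl$merge_candidate) "merge_candidate"
            else ""
    data.frame(family = cl$members, cluster = cid,
               dominant_clan = ifelse(is.na(cl$dominant_clan), "",
                                      cl$dominant_clan),
               new_member_candidate =
                 cl$members %in% cl$new_member_candidates,
               cluster_flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(family = character(0), cluster = character(0),
                      dominant_clan = character(0),
                      new_member_candidate = logical(0),
                      cluster_flag = character(0))
  }
  out
}

#' Adjusted Rand index between two labelings
#'
#' Closed-form ARI from the contingency table; 1 for identical partitions,
#' ~0 for independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type)
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
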