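#' Build a thresholded shared-patient provider graph for one service area
#'
#' Two primary-care providers are connected when at least `min_shared`
#' distinct patients have at least one qualifying primary-care visit claim
#' billed by each of them. Edge weight is the shared-patient count. Qualifying
#' visits are office-visit CPT codes; qualifying providers are primary-care
#' physicians (CMS specialties 01, 08, 11, 38) and NPs/PAs (50, 97) with a
#' primary-care taxonomy flag.
#'
#' @param visits visit-claim table (`patient_id`, `provider_id`,
#'   `service_date`, `cpt_code`). Restrict to the analysis year before
#'   calling, or pass `year`.
#' @param providers provider table (`provider_id`, `area_id`,
#'   `specialty_code`, `primary_care_taxonomy`).
#' @param area_id the service area to build.
#' @param min_shared minimum distinct shared patients for an edge (default 30).
#' @param codesets a [codeset_config()]; `office_visit_cpt` defines
#'   qualifying visits.
#' @param year optional calendar year filter applied to `service_date`.
#' @return An object of class `shared_patient_graph`: list with `area_id`,
#'   `nodes` (all qualifying providers with >= 1 qualifying visit in the
#'   area), `edges` (data.frame `provider_a`, `provider_b`, `weight`) and
#'   `threshold`.
#' @export
build_shared_patient_graph <- function(visits, providers, area_id,
                                       min_shared = 30,
                                       codesets = codeset_config(),
                                       year = NULL) {
  unknown <- setdiff(unique(visits$provider_id), providers$provider_id)
  if (length(unknown) > 0)
    stop("visit claims reference unknown provider(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  pc <- is_primary_care(providers)
  prov_area <- providers[pc & providers$area_id == area_id, ]
  v <- visits[visits$cpt_code %in% codesets$office_visit_cpt &
                visits$provider_id %in% prov_area$provider_id, ]
  if (!is.null(year))
    v <- v[format(v$service_date, "%Y") == as.character(year), ]
  nodes <- sort(unique(v$provider_id))
  if (nrow(v) == 0) {
    g <- list(area_id = area_id, nodes = character(0),
              edges = data.frame(provider_a = character(0),
                                 provider_b = character(0),
                                 weight = numeric(0)),
              threshold = min_shared)
    class(g) <- "shared_patient_graph"
    return(g)
  }
  inc <- table(v$patient_id, v$provider_id) > 0
  shared <- crossprod(inc)             # distinct shared patients per pair
  ut <- upper.tri(shared)
  keep <- which(ut & shared >= min_shared, arr.ind = TRUE)
  edges <- data.frame(provider_a = rownames(shared)[keep[, 1]],
                      provider_b = colnames(shared)[keep[, 2]],
                      weight = shared[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$provider_a, edges$provider_b), ]
  rownames(edges) <- NULL
  g <- list(area_id = area_id, nodes = nodes, edges = edges,
            threshold = min_shared)
  class(g) <- "shared_patient_graph"
  g
}

is_primary_care <- function(providers) {
  providers$specialty_code %in% PCP_SPECIALTIES |
    (providers$specialty_code %in% c(NP_SPECIALTY, PA_SPECIALTY) &
       providers$primary_care_taxonomy)
}

#' @export
print.shared_patient_graph <- function(x, ...) {
  cat(sprintf("Shared-patient graph, area %s: %d providers, %d edges (>= %d shared patients)\n",
              x$area_id, length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(graph$edges[, c("provider_a", "provider_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = graph$nodes))
  igraph::E(g)$weight <- graph$edges$weight
  g
}

#' Walktrap community detection on a shared-patient graph
#'
#' Random-walk agglomerative clustering (Pons-Latapy) on the weighted graph,
#' cut at the maximum-modularity merge level. Providers with no edge at the
#' sharing threshold form singleton clusters; clusters never span
#' disconnected components.
#'
#' @param graph a `shared_patient_graph`.
#' @param walk_length random-walk length (default 4).
#' @param weighted use shared-patient counts as edge weights (default TRUE);
#'   FALSE treats every retained edge as weight 1.
#' @return Named character-to-integer mapping: cluster id per provider.
#' @export
walktrap_communities <- function(graph, walk_length = 4, weighted = TRUE) {
  stopifnot(inherits(graph, "shared_patient_graph"))
  if (walk_length < 1) stop("'walk_length' must be >= 1")
  if (length(graph$nodes) == 0) return(stats::setNames(integer(0), character(0)))
  g <- as_igraph(graph)
  deg <- igraph::degree(g)
  member <- stats::setNames(rep(NA_integer_, length(graph$nodes)), graph$nodes)
  if (any(deg > 0)) {
    sub <- igraph::induced_subgraph(g, igraph::V(g)[deg > 0])
    wt <- igraph::cluster_walktrap(
      sub, steps = walk_length,
      weights = if (weighted) igraph::E(sub)$weight else NA)
    member[igraph::V(sub)$name] <- igraph::membership(wt)
  }
  iso <- is.na(member)
  member[iso] <- max(member, 0L, na.rm = TRUE) + seq_len(sum(iso))
  member
}

#' Newman modularity of a weighted partition
#'
#' \deqn{Q = \sum_c \left( \frac{w_{in}(c)}{W} - \left(\frac{s(c)}{2W}\right)^2 \right)}
#' with `W` the total edge weight, `w_in(c)` the weight inside cluster `c` and
#' `s(c)` the summed weighted degree of its members.
#'
#' @param graph a `shared_patient_graph`.
#' @param partition named vector (cluster label per provider) covering all
#'   nodes.
#' @param weighted evaluate on shared-patient weights (default TRUE).
#' @return Modularity in `[-0.5, 1]`; `NA` for an edgeless graph.
#' @export
modularity_q <- function(graph, partition, weighted = TRUE) {
  stopifnot(inherits(graph, "shared_patient_graph"))
  missing <- setdiff(graph$nodes, names(partition))
  if (length(missing) > 0)
    stop("partition is missing node(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  e <- graph$edges
  if (nrow(e) == 0) return(NA_real_)
  w <- if (weighted) e$weight else rep(1, nrow(e))
  W <- sum(w)
  part <- as.character(partition[graph$nodes])
  names(part) <- graph$nodes
  clusters <- unique(part)
  win <- stats::setNames(numeric(length(clusters)), clusters)
  same <- part[e$provider_a] == part[e$provider_b]
  if (any(same)) {
    tw <- tapply(w[same], part[e$provider_a][same], sum)
    win[names(tw)] <- tw
  }
  strength <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  ts <- tapply(c(w, w), c(e$provider_a, e$provider_b), sum)
  strength[names(ts)] <- ts
  sc <- tapply(strength, part, sum)
  scv <- stats::setNames(numeric(length(clusters)), clusters)
  scv[names(sc)] <- sc
  sum(win / W - (scv / (2 * W))^2)
}

#' Identify candidate practices in every service area
#'
#' Runs the full identification stage: per-area shared-patient graph,
#' Walktrap clustering, and modularity evaluation of the resulting partition.
#'
#' @param visits,providers claim and provider tables (see
#'   [build_shared_patient_graph()]).
#' @param codesets a [codeset_config()].
#' @param year calendar year of claims used for identification (default 2015).
#' @param min_shared edge threshold (default 30 shared patients).
#' @param walk_length Walktrap walk length (default 4).
#' @param weighted weighted graph/modularity (default TRUE).
#' @param gate modularity gate (default 0.4, inclusive).
#' @return List of per-area partition results: each has `area_id`, `graph`,
#'   `membership`, `modularity`, `passed_gate`.
#' @export
identify_practices <- function(visits, providers, codesets = codeset_config(),
                               year = 2015, min_shared = 30, walk_length = 4,
                               weighted = TRUE, gate = 0.4) {
  pc <- is_primary_care(providers)
  areas <- sort(unique(providers$area_id[pc]))
  out <- vector("list", length(areas))
  names(out) <- areas
  for (a in areas) {
    g <- build_shared_patient_graph(visits, providers, a,
                                    min_shared = min_shared,
                                    codesets = codesets, year = year)
    memb <- walktrap_communities(g, walk_length = walk_length,
                                 weighted = weighted)
    q <- if (length(memb) > 0) modularity_q(g, memb, weighted = weighted)
         else NA_real_
    out[[a]] <- list(area_id = a, graph = g, membership = memb,
                     modularity = q,
                     passed_gate = isTRUE(q >= gate))
  }
  out
}

#' Classify a practice's team composition from member specialty codes
#'
#' The four study compositions: `PCP` (only specialties 01/08/11/38),
#' `PCP_NP` (PCPs plus NPs, no PAs), `PCP_NP_PA` (all three roles),
#' `PCP_PA` (PCPs plus PAs, no NPs). Anything else (e.g. NP-only) is
#' `other` and excluded downstream.
#'
#' @param member_specialties character vector (multiset) of CMS specialty
#'   codes of the practice's members.
#' @return One of `"PCP"`, `"PCP_NP"`, `"PCP_NP_PA"`, `"PCP_PA"`, `"other"`.
#' @export
classify_team_type <- function(member_specialties) {
  if (length(member_specialties) == 0)
    stop("cannot classify an empty practice")
  valid <- c(PCP_SPECIALTIES, NP_SPECIALTY, PA_SPECIALTY)
  bad <- setdiff(unique(member_specialties), valid)
  if (length(bad) > 0)
    stop("unknown specialty code(s): ", paste(bad, collapse = ", "))
  has_pcp <- any(member_specialties %in% PCP_SPECIALTIES)
  has_np <- any(member_specialties == NP_SPECIALTY)
  has_pa <- any(member_specialties == PA_SPECIALTY)
  if (!has_pcp) return("other")
  if (has_np && has_pa) return("PCP_NP_PA")
  if (has_np) return("PCP_NP")
  if (has_pa) return("PCP_PA")
  "PCP"
}

#' Gate areas on modularity and assemble practice assignments
#'
#' Applies the practice-level exclusion cascade in fixed order: (1) drop all
#' clusters of areas whose partition modularity is below the gate; (2) drop
#' solo-provider clusters; (3) drop clusters containing a provider that
#' appears in more than one cluster across areas; (4) classify team type and
#' drop compositions outside the four study types; (5) when attributed
#' diabetic-patient counts are supplied, drop practices below `min_patients`.
#' Each excluded practice carries the first failing reason.
#'
#' @param partitions result of [identify_practices()].
#' @param providers provider table (for specialty codes).
#' @param gate modularity gate, inclusive (default 0.4).
#' @param min_patients minimum attributed diabetic patients (default 20).
#' @param attributed_counts optional named vector: attributed diabetic
#'   patients per practice id. When `NULL` the size filter is skipped (the
#'   pipeline attributes patients first, then re-applies it).
#' @return An object of class `practice_set`: list with `practices` (one row
#'   per candidate practice: `practice_id`, `area_id`, `n_providers`,
#'   `team_type`, `modularity`, `n_attributed`, `included`,
#'   `exclusion_reason`) and `membership` (`provider_id`, `practice_id`).
#' @export
gate_and_assign <- function(partitions, providers, gate = 0.4,
                            min_patients = 20, attributed_counts = NULL) {
  rows <- list(); memb_rows <- list()
  for (p in partitions) {
    if (length(p$membership) == 0) next
    cl <- split(names(p$membership), p$membership)
    ids <- sprintf("%s_C%02d", p$area_id, seq_along(cl))
    for (i in seq_along(cl)) {
      rows[[length(rows) + 1]] <- data.frame(
        practice_id = ids[i], area_id = p$area_id,
        n_providers = length(cl[[i]]),
        modularity = p$modularity,
        area_passed_gate = isTRUE(p$modularity >= gate),
        stringsAsFactors = FALSE)
      memb_rows[[length(memb_rows) + 1]] <- data.frame(
        provider_id = cl[[i]], practice_id = ids[i],
        stringsAsFactors = FALSE)
    }
  }
  practices <- do.call(rbind, rows)
  membership <- do.call(rbind, memb_rows)
  if (is.null(practices)) {
    practices <- data.frame(practice_id = character(0), area_id = character(0),
                            n_providers = integer(0), modularity = numeric(0),
                            area_passed_gate = logical(0))
    membership <- data.frame(provider_id = character(0),
                             practice_id = character(0))
  }

  spec <- stats::setNames(providers$specialty_code, providers$provider_id)
  practices$team_type <- vapply(practices$practice_id, function(pid) {
    classify_team_type(spec[membership$provider_id[membership$practice_id == pid]])
  }, character(1))
  practices$n_attributed <- if (is.null(attributed_counts)) NA_integer_ else {
    n <- attributed_counts[practices$practice_id]
    n[is.na(n)] <- 0L
    as.integer(n)
  }

  reason <- rep("none", nrow(practices))
  reason[practices$n_providers == 1 & reason == "none"] <- "solo_provider"
  # cross-practice providers, judged among clusters of gate-passing areas
  ok_area <- practices$area_passed_gate
  memb_ok <- membership[membership$practice_id %in%
                          practices$practice_id[ok_area], ]
  dup_prov <- unique(memb_ok$provider_id[duplicated(memb_ok$provider_id)])
  if (length(dup_prov) > 0) {
    hit <- unique(memb_ok$practice_id[memb_ok$provider_id %in% dup_prov])
    reason[practices$practice_id %in% hit & reason == "none"] <-
      "cross_practice_provider"
  }
  reason[practices$team_type == "other" & reason == "none"] <- "team_type_other"
  if (!is.null(attributed_counts))
    reason[practices$n_attributed < min_patients & reason == "none"] <-
      "too_few_patients"
  reason[!practices$area_passed_gate] <- "failed_modularity_gate"
  practices$exclusion_reason <- reason
  practices$included <- reason == "none"
  practices <- practices[, c("practice_id", "area_id", "n_providers",
                             "team_type", "modularity", "n_attributed",
                             "included", "exclusion_reason")]
  rownames(practices) <- NULL
  out <- list(practices = practices, membership = membership)
  class(out) <- "practice_set"
  out
}

#' Assemble a practice_set from its two tables
#'
#' Rebuilds the object written as `practices.csv` / `practice_membership.csv`
#' so pipeline stages can be resumed from disk.
#'
#' @param practices practice table (see [gate_and_assign()]).
#' @param membership provider-to-practice table.
#' @return A `practice_set`.
#' @export
practice_set <- function(practices, membership) {
  stopifnot(all(c("practice_id", "included", "team_type") %in%
                  names(practices)),
            all(c("provider_id", "practice_id") %in% names(membership)))
  out <- list(practices = practices, membership = membership)
  class(out) <- "practice_set"
  out
}

#' @export
print.practice_set <- function(x, ...) {
  p <- x$practices
  cat(sprintf("Practice set: %d candidate clusters, %d included\n",
              nrow(p), sum(p$included)))
  if (nrow(p) > 0) print(table(exclusion_reason = p$exclusion_reason))
  invisible(x)
}

#' Adjusted Rand index between two provider partitions
#'
#' @param a,b named cluster-label vectors; compared over the providers named
#'   in both.
#' @return The adjusted Rand index (1 = identical partitions).
#' @export
partition_ari <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (length(common) == 0) stop("partitions share no providers")
  igraph::compare(as.integer(factor(a[common])),
                  as.integer(factor(b[common])),
                  method = "adjusted.rand")
}

#' Write a shared-patient graph as a weighted edge-list TSV
#'
#' @param graph a `shared_patient_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
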