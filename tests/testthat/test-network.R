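providers_toy <- function(ids, area = "A1", specialty = "08", tax = FALSE) {
  data.frame(provider_id = ids, area_id = area, specialty_code = specialty,
             primary_care_taxonomy = tax, practice_id = NA,
             stringsAsFactors = FALSE)
}

visits_for <- function(pat, prov, date = "2015-03-01", cpt = "99213") {
  data.frame(patient_id = pat, provider_id = prov,
             service_date = as.Date(date), cpt_code = cpt, setting = "office",
             snf_biller = FALSE, stringsAsFactors = FALSE)
}

test_that("shared-patient edges require the threshold of distinct patients", {
  prov <- providers_toy(c("A", "B"))
  pats <- sprintf("q%02d", 1:30)
  v <- rbind(visits_for(pats, "A"), visits_for(pats, "B"))
  g <- build_shared_patient_graph(v, prov, "A1", min_shared = 30)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 30)

  v29 <- v[v$patient_id != "q30", ]
  g29 <- build_shared_patient_graph(v29, prov, "A1", min_shared = 30)
  expect_equal(nrow(g29$edges), 0)

  # repeat visits by the same patient do not inflate the count
  vdup <- rbind(v29, visits_for(pats[1:5], "A", "2015-06-01"))
  gdup <- build_shared_patient_graph(vdup, prov, "A1", min_shared = 30)
  expect_equal(nrow(gdup$edges), 0)
})

test_that("graph edges match a brute-force pairwise intersection oracle", {
  prov <- providers_toy(c("A", "B", "C"))
  v <- rbind(visits_for(sprintf("s%02d", 1:35), "A"),
             visits_for(sprintf("s%02d", 1:35), "B"),
             visits_for(sprintf("t%02d", 1:27), "B"),
             visits_for(c(sprintf("t%02d", 1:27), sprintf("s%02d", 1:4)), "C"),
             visits_for("s05", "C"))
  g <- build_shared_patient_graph(v, prov, "A1", min_shared = 30)
  oracle <- oracle_shared_counts(v, c("A", "B", "C"))
  expected <- oracle[oracle$shared >= 30, c("provider_a", "provider_b", "shared")]
  expect_equal(nrow(g$edges), 2)
  got <- g$edges[order(g$edges$provider_a), ]
  expect_equal(got$provider_a, expected$provider_a)
  expect_equal(got$weight, expected$shared)
  # A-C shared 5 < 30: absent
  expect_false(any(got$provider_a == "A" & got$provider_b == "C"))
})

test_that("non-primary-care providers and non-office codes are excluded from the graph", {
  prov <- rbind(providers_toy(c("A", "B")),
                providers_toy("NPx", specialty = "50", tax = FALSE),
                providers_toy("NPy", specialty = "50", tax = TRUE),
                providers_toy("CARD", specialty = "06"))
  pats <- sprintf("u%02d", 1:40)
  v <- rbind(visits_for(pats, "A"), visits_for(pats, "B"),
             visits_for(pats, "NPx"), visits_for(pats, "NPy"),
             visits_for(pats, "CARD"),
             visits_for(pats, "A", cpt = "99243"))  # consult: not qualifying
  g <- build_shared_patient_graph(v, prov, "A1", min_shared = 30)
  expect_setequal(g$nodes, c("A", "B", "NPy"))
  expect_false("NPx" %in% g$nodes)      # NP without primary-care taxonomy
  expect_false("CARD" %in% g$nodes)     # specialist
  expect_error(build_shared_patient_graph(
    visits_for("p1", "GHOST"), prov, "A1"), "GHOST")
})

test_that("raising the sharing threshold never adds an edge", {
  b <- simulate_claims(small_config(seed = 31))
  g10 <- build_shared_patient_graph(b$visits, b$providers, "A01",
                                    min_shared = 10, year = 2015)
  g30 <- build_shared_patient_graph(b$visits, b$providers, "A01",
                                    min_shared = 30, year = 2015)
  key <- function(g) paste(g$edges$provider_a, g$edges$provider_b)
  expect_true(all(key(g30) %in% key(g10)))
  expect_true(all(g30$edges$weight >= 30))
})

test_that("modularity matches hand-derived and brute-force values", {
  # two unit-weight triangles joined by one bridge
  tri2 <- toy_graph(edge_df(c("a", "a", "b", "d", "d", "e", "c"),
                            c("b", "c", "c", "e", "f", "f", "d")))
  part <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  expect_equal(modularity_q(tri2, part), 6 / 7 - 1 / 2, tolerance = 1e-12)
  expect_equal(modularity_q(tri2, part), oracle_modularity(tri2, part),
               tolerance = 1e-12)
  # all nodes in one cluster: Q = 0
  expect_equal(modularity_q(tri2, c(a = 1, b = 1, c = 1, d = 1, e = 1, f = 1)),
               0, tolerance = 1e-12)
  # singletons in a loop-free graph: strictly negative
  singl <- stats::setNames(1:6, names(part))
  expect_lt(modularity_q(tri2, singl), 0)
  expect_equal(modularity_q(tri2, singl), oracle_modularity(tri2, singl),
               tolerance = 1e-12)
  # missing node is named in the error
  expect_error(modularity_q(tri2, part[-6]), "f")
})

test_that("modularity agrees with igraph and the oracle on random weighted graphs", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(4:9, 1)
    nodes <- paste0("v", seq_len(n))
    pairs <- utils::combn(nodes, 2)
    keep <- runif(ncol(pairs)) < 0.5
    if (!any(keep)) next
    e <- edge_df(pairs[1, keep], pairs[2, keep],
                 w = sample(1:40, sum(keep), replace = TRUE))
    g <- toy_graph(e, nodes = nodes)
    part <- stats::setNames(sample(1:3, n, replace = TRUE), nodes)
    q <- modularity_q(g, part)
    expect_equal(q, oracle_modularity(g, part), tolerance = 1e-12)
    ig <- igraph::graph_from_data_frame(e[, 1:2], directed = FALSE,
                                        vertices = data.frame(name = nodes))
    q_ig <- igraph::modularity(ig, part[nodes], weights = e$weight)
    expect_equal(q, q_ig, tolerance = 1e-12)
  }
})

test_that("walktrap recovers designed toy structures at the exhaustive optimum", {
  # two 5-cliques joined by a single bridge
  cl1 <- utils::combn(paste0("a", 1:5), 2)
  cl2 <- utils::combn(paste0("b", 1:5), 2)
  e <- rbind(edge_df(cl1[1, ], cl1[2, ]), edge_df(cl2[1, ], cl2[2, ]),
             edge_df("a1", "b1"))
  g <- toy_graph(e)
  memb <- walktrap_communities(g)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[paste0("a", 1:5)])), 1)
  expect_equal(length(unique(memb[paste0("b", 1:5)])), 1)

  # a single triangle stays one cluster
  tri <- toy_graph(edge_df(c("x", "x", "y"), c("y", "z", "z")))
  expect_equal(length(unique(walktrap_communities(tri))), 1)

  # two disconnected edges never merge across components
  disc <- toy_graph(edge_df(c("p", "r"), c("q", "s")))
  md <- walktrap_communities(disc)
  expect_false(md["p"] == md["r"])

  expect_error(walktrap_communities(tri, walk_length = 0), "walk_length")
})

test_that("walktrap attains the exhaustive maximum modularity on a designed suite", {
  suite <- list(
    two_triangle_bridge = toy_graph(edge_df(
      c("a", "a", "b", "d", "d", "e", "c"),
      c("b", "c", "c", "e", "f", "f", "d"))),
    weighted_pair = toy_graph(edge_df(
      c("a", "a", "b", "c", "d", "d", "e"),
      c("b", "c", "c", "d", "e", "f", "f"),
      w = c(30, 35, 31, 2, 33, 30, 34))),
    two_components = toy_graph(rbind(
      edge_df(c("a", "a", "b"), c("b", "c", "c")),
      edge_df(c("p", "p", "q"), c("q", "r", "r"))))
  )
  for (nm in names(suite)) {
    g <- suite[[nm]]
    memb <- walktrap_communities(g)
    q_wt <- modularity_q(g, memb)
    q_best <- oracle_max_modularity(g)$q
    expect_equal(q_wt, q_best, tolerance = 1e-9, info = nm)
  }
})

test_that("relabeling providers permutes but never changes weights, Q or clusters", {
  b <- simulate_claims(sim_config(n_service_areas = 1, practices_per_area = 4,
                                  patients_per_practice = 40, seed = 17))
  g <- build_shared_patient_graph(b$visits, b$providers, "A01", year = 2015)
  memb <- walktrap_communities(g)
  q <- modularity_q(g, memb)

  relab <- stats::setNames(sprintf("Z%03d", rev(seq_along(g$nodes))), g$nodes)
  prov2 <- b$providers
  prov2$provider_id <- ifelse(prov2$provider_id %in% names(relab),
                              relab[prov2$provider_id], prov2$provider_id)
  vis2 <- b$visits
  vis2$provider_id <- ifelse(vis2$provider_id %in% names(relab),
                             relab[vis2$provider_id], vis2$provider_id)
  g2 <- build_shared_patient_graph(vis2, prov2, "A01", year = 2015)
  w1 <- sort(g$edges$weight); w2 <- sort(g2$edges$weight)
  expect_equal(w1, w2)
  memb2 <- walktrap_communities(g2)
  expect_equal(modularity_q(g2, memb2), q, tolerance = 1e-9)
  # cluster contents identical up to the relabeling
  expect_equal(partition_ari(memb2, stats::setNames(memb[names(relab)],
                                                    relab)), 1)
})

test_that("team types derive from member specialty compositions", {
  expect_equal(classify_team_type(c("08", "08", "11")), "PCP")
  expect_equal(classify_team_type(c("11", "50", "97")), "PCP_NP_PA")
  expect_equal(classify_team_type(c("01", "50")), "PCP_NP")
  expect_equal(classify_team_type(c("38", "97")), "PCP_PA")
  expect_equal(classify_team_type(c("50", "50")), "other")
  expect_equal(classify_team_type(c("50", "97")), "other")
  expect_error(classify_team_type(c("08", "99")), "99")
  expect_error(classify_team_type(character(0)))
})

test_that("gating applies exclusions in fixed order with first-fail reasons", {
  mk_part <- function(area, memb, q) {
    g <- toy_graph(edge_df(character(0), character(0), numeric(0)),
                   nodes = names(memb))
    g$area_id <- area
    list(area_id = area, graph = g, membership = memb, modularity = q,
         passed_gate = q >= 0.4)
  }
  prov <- rbind(
    providers_toy(c("a1", "a2", "b1", "b2", "solo"), area = "A1"),
    providers_toy(c("n1", "n2"), area = "A1", specialty = "50", tax = TRUE),
    providers_toy(c("c1", "c2", "dup"), area = "A2"),
    providers_toy("dup2", area = "A3"))
  parts <- list(
    mk_part("A1", c(a1 = 1, a2 = 1, b1 = 2, b2 = 2, solo = 3,
                    n1 = 4, n2 = 4), 0.55),
    mk_part("A2", c(c1 = 1, c2 = 1, dup = 1), 0.62),
    mk_part("A3", c(dup = 1, dup2 = 1), 0.39))   # area fails the gate
  counts <- c(A1_C01 = 25, A1_C02 = 10, A2_C01 = 30)
  ps <- gate_and_assign(parts, prov, gate = 0.4, min_patients = 20,
                        attributed_counts = counts)
  p <- ps$practices
  get <- function(id, col) p[p$practice_id == id, col]
  expect_true(get("A1_C01", "included"))
  expect_equal(get("A1_C02", "exclusion_reason"), "too_few_patients")
  expect_equal(get("A1_C03", "exclusion_reason"), "solo_provider")
  expect_equal(get("A1_C04", "exclusion_reason"), "team_type_other") # NP-only
  # all clusters of the failing area carry the gate reason, including the one
  # that shares provider 'dup' with A2
  expect_true(all(get("A3_C01", "exclusion_reason") == "failed_modularity_gate"))
  # 'dup' sits in clusters of two gate-passing areas? A3 failed, so A2's
  # cluster survives the cross-practice check and passes
  expect_true(get("A2_C01", "included"))
})

test_that("a provider in clusters of two gate-passing areas voids both clusters", {
  mk_part <- function(area, memb, q) {
    g <- toy_graph(edge_df(character(0), character(0), numeric(0)),
                   nodes = names(memb))
    g$area_id <- area
    list(area_id = area, graph = g, membership = memb, modularity = q,
         passed_gate = TRUE)
  }
  prov <- rbind(providers_toy(c("a1", "a2", "dup"), area = "A1"),
                providers_toy(c("b1", "b2"), area = "A2"))
  parts <- list(mk_part("A1", c(a1 = 1, a2 = 1, dup = 1), 0.5),
                mk_part("A2", c(b1 = 1, b2 = 1, dup = 1), 0.5))
  ps <- gate_and_assign(parts, prov, attributed_counts = c(A1_C01 = 30,
                                                           A2_C01 = 30))
  expect_equal(ps$practices$exclusion_reason,
               rep("cross_practice_provider", 2))
})
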