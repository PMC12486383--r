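one_gene_hyp <- function() ancestral_hypothesis(
  "one", data.frame(label = "X", strand = "+"), mapping = list(X = "LWS"))

jawed_struct <- scenario_structure(groups = list(jawed = list(copies = 2)))
full_struct <- scenario_structure()

obs_from <- function(...) {
  rows <- list(...)
  observed_arrangement(do.call(rbind, lapply(rows, function(r)
    data.frame(group = r[[1]], chrom = r[[2]], clade = r[[3]],
               pos = as.integer(r[[4]]), subtype = r[[5]], strand = r[[6]],
               stringsAsFactors = FALSE))))
}

jawed_pattern <- obs_from(
  list("jawed", "d1", "1", 1, "RH1", "+"),
  list("jawed", "d2", "1", 1, "SWS2", "+"),
  list("jawed", "d2", "1", 2, "LWS", "+"),
  list("jawed", "d3", "2", 1, "RH2", "+"),
  list("jawed", "d4", "2", 1, "SWS1", "+"))

full_pattern <- obs_from(
  list("jawless", "cA", "1", 1, "RH1", "+"),
  list("jawless", "cA", "1", 2, "LWS", "+"),
  list("jawless", "cB", "2", 1, "SWS2", "+"),
  list("jawless", "cB", "2", 2, "RH2", "+"),
  list("jawless", "cX", "other", 1, "SWS1", "+"),
  list("jawed", "d1", "1", 1, "RH1", "+"),
  list("jawed", "d2", "1", 1, "SWS2", "+"),
  list("jawed", "d2", "1", 2, "LWS", "+"),
  list("jawed", "d3", "2", 1, "RH2", "+"),
  list("jawed", "d4", "2", 1, "SWS1", "+"))

test_that("replay applies WGD structure and events deterministically", {
  ## one gene, no events: every leaf carries it
  r <- replay(one_gene_hyp(), NULL, jawed_struct)
  expect_equal(length(r$leaves), 4)
  expect_true(all(vapply(r$leaves, nrow, 0L) == 1))
  ## 1R alone gives two chromosomes in a single-copy group
  solo <- scenario_structure(groups = list(anc = list(copies = 1)))
  r1 <- replay(one_gene_hyp(), NULL, solo)
  expect_equal(names(r1$leaves), c("anc.1.1", "anc.2.1"))
  ## (LWS, AO) + 1R + 2R, no losses: four chromosomes each with the
  ## tandem pair in ancestral order and orientation
  hyp <- ancestral_hypothesis(
    "b", data.frame(label = c("LWS", "AO"), strand = "+"),
    mapping = list(LWS = "LWS", AO = c("SWS1", "SWS2", "RH1", "RH2")))
  r2 <- replay(hyp, NULL, jawed_struct)
  for (lf in r2$leaves) {
    expect_equal(lf$label, c("LWS", "AO"))
    expect_equal(lf$strand, c("+", "+"))
  }
  ## losses and translocations consume the right gene instances
  ev <- data.frame(kind = c("LOSS", "TRANSLOCATION"),
                   edge = c("stem.1", "jawed.2.1"),
                   uid = c("LWS#1", "AO#2"), new_uid = NA,
                   to_chrom = c(NA, "elsewhere"), new_strand = c(NA, "-"))
  r3 <- replay(hyp, ev, jawed_struct)
  expect_equal(r3$leaves[["jawed.1.1"]]$label, "AO")
  expect_equal(r3$leaves[["jawed.2.1"]]$label, "LWS")
  expect_equal(r3$other$elsewhere$uid, "AO#2")
  expect_equal(r3$other$elsewhere$strand, "-")
  ## referencing a gene already gone is an error
  bad <- data.frame(kind = "LOSS", edge = "jawed.1.1", uid = "LWS#1",
                    new_uid = NA, to_chrom = NA, new_strand = NA)
  expect_error(replay(hyp, rbind(ev[1, ], bad), jawed_struct), "absent")
  ## tandem duplications are pre-1R only
  dup <- data.frame(kind = "TANDEM_DUP", edge = "stem.1", uid = "LWS#1",
                    new_uid = "LWS#1.d1", to_chrom = NA, new_strand = NA)
  expect_error(replay(hyp, dup, jawed_struct), "pre-1R")
})

test_that("zero-event observations cost zero and infeasible subtypes cost Inf", {
  hyp <- ancestral_hypothesis(
    "b", data.frame(label = c("LWS", "AO"), strand = "+"),
    mapping = list(LWS = "LWS", AO = c("SWS1", "SWS2", "RH1", "RH2")))
  ## the untouched replay observed exactly
  obs0 <- obs_from(
    list("jawed", "c1", "1", 1, "LWS", "+"), list("jawed", "c1", "1", 2, "RH1", "+"),
    list("jawed", "c2", "1", 1, "LWS", "+"), list("jawed", "c2", "1", 2, "RH1", "+"),
    list("jawed", "c3", "2", 1, "LWS", "+"), list("jawed", "c3", "2", 2, "RH2", "+"),
    list("jawed", "c4", "2", 1, "LWS", "+"), list("jawed", "c4", "2", 2, "RH2", "+"))
  r <- min_cost_scenario(obs0, hyp, struct = jawed_struct)
  expect_true(r$feasible)
  expect_equal(r$cost, 0)
  ## a subtype outside every mapping: explicit infeasibility, not an error
  obs_bad <- obs_from(list("jawed", "c1", "1", 1, "PIN", "+"))
  rb <- min_cost_scenario(obs_bad, hyp, struct = jawed_struct)
  expect_false(rb$feasible)
  expect_equal(rb$cost, Inf)
})

test_that("single-loss instances agree with the flat enumeration oracle", {
  hyp <- ancestral_hypothesis(
    "b", data.frame(label = c("LWS", "AO"), strand = "+"),
    mapping = list(LWS = "LWS", AO = c("SWS1", "SWS2", "RH1", "RH2")))
  ## zero-loss replay minus one gene on one chromosome
  obs1 <- obs_from(
    list("jawed", "c1", "1", 1, "LWS", "+"),
    list("jawed", "c1", "1", 2, "RH1", "+"),
    list("jawed", "c2", "1", 1, "RH1", "+"),
    list("jawed", "c3", "2", 1, "LWS", "+"), list("jawed", "c3", "2", 2, "RH2", "+"),
    list("jawed", "c4", "2", 1, "LWS", "+"), list("jawed", "c4", "2", 2, "RH2", "+"))
  r <- min_cost_scenario(obs1, hyp, struct = jawed_struct)
  expect_equal(r$cost, 1)
  expect_equal(oracle_min_cost(obs1, hyp, jawed_struct, max_cost = 3), 1)
  ## every returned scenario replays exactly to the observation
  for (sc in r$scenarios) {
    rep_out <- replay(hyp, sc$events, jawed_struct)
    expect_true(replay_matches(rep_out, sc$assignment, obs1, jawed_struct))
  }
})

test_that("engine cost equals the flat oracle on random small instances", {
  hyp <- ancestral_hypothesis(
    "h", data.frame(label = c("A", "B"), strand = "+"),
    mapping = list(A = c("RH1", "RH2"), B = "LWS"))
  solo2 <- scenario_structure(groups = list(g1 = list(copies = 2)))
  set.seed(60)
  edges <- c("pre1R", "stem.1", "stem.2", "g1.1", "g1.2",
             "g1.1.1", "g1.1.2", "g1.2.1", "g1.2.2")
  uids <- c("A#1", "B#2")
  checked <- 0
  for (trial in 1:40) {
    n_ev <- sample(0:2, 1)
    ev <- NULL
    if (n_ev) {
      pick <- data.frame(edge = sample(edges, n_ev, replace = TRUE),
                         uid = sample(uids, n_ev, replace = TRUE))
      ev <- data.frame(kind = "LOSS", edge = pick$edge, uid = pick$uid,
                       new_uid = NA, to_chrom = NA, new_strand = NA,
                       stringsAsFactors = FALSE)
    }
    rep_out <- tryCatch(replay(hyp, ev, solo2), error = function(e) NULL)
    if (is.null(rep_out)) next
    ## observe the replay with truth-like subtypes (RH1 on clade 1, RH2 on 2)
    rows <- list()
    for (lf in names(rep_out$leaves)) {
      st <- rep_out$leaves[[lf]]
      if (!nrow(st)) next
      clade <- strsplit(lf, ".", fixed = TRUE)[[1]][2]
      subt <- ifelse(st$label == "B", "LWS", ifelse(clade == "1", "RH1", "RH2"))
      for (i in seq_len(nrow(st)))
        rows[[length(rows) + 1L]] <- data.frame(
          group = "g1", chrom = lf, clade = clade, pos = i,
          subtype = subt[i], strand = st$strand[i], stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    obs <- observed_arrangement(do.call(rbind, rows))
    r <- min_cost_scenario(obs, hyp, struct = solo2)
    oc <- oracle_min_cost(obs, hyp, solo2, max_cost = 3)
    expect_equal(r$cost, oc, info = paste("trial", trial))
    expect_lte(r$cost, n_ev)
    for (sc in r$scenarios[seq_len(min(3, length(r$scenarios)))]) {
      ro <- replay(hyp, sc$events, solo2)
      expect_true(replay_matches(ro, sc$assignment, obs, solo2))
    }
    checked <- checked + 1
  }
  expect_gte(checked, 20)
})

test_that("the jawed pattern costs more under the five-gene hypothesis", {
  hyps <- opsin_hypotheses()
  rA <- min_cost_scenario(jawed_pattern, hyps$stepwise_five,
                          struct = jawed_struct)
  rB <- min_cost_scenario(jawed_pattern, hyps$two_gene, struct = jawed_struct)
  expect_gt(rA$cost, rB$cost)
  ## soundness of both optima
  for (r in list(rA, rB)) {
    h <- hyps[[r$hypothesis]]
    sc <- r$scenarios[[1]]
    dup_ev <- sc$events[sc$events$kind == "TANDEM_DUP", , drop = FALSE]
    ro <- replay(h, sc$events, jawed_struct)
    expect_true(replay_matches(ro, sc$assignment, jawed_pattern, jawed_struct))
  }
})

test_that("weight changes act monotonically and scale invariance holds", {
  hyps <- opsin_hypotheses()
  w1 <- c(TANDEM_DUP = 1, LOSS = 1, TRANSLOCATION = 1)
  w2 <- c(TANDEM_DUP = 1, LOSS = 2, TRANSLOCATION = 1)
  for (h in hyps[c("stepwise_five", "two_gene")]) {
    c1 <- min_cost_scenario(jawed_pattern, h, weights = w1,
                            struct = jawed_struct)$cost
    c2 <- min_cost_scenario(jawed_pattern, h, weights = w2,
                            struct = jawed_struct)$cost
    expect_gte(c2, c1)
  }
  ## uniform scaling leaves the ranking unchanged
  t1 <- compare_hypotheses(jawed_pattern, hyps[c("stepwise_five", "two_gene")],
                           weights = w1, struct = jawed_struct)
  t3 <- compare_hypotheses(jawed_pattern, hyps[c("stepwise_five", "two_gene")],
                           weights = w1 * 3, struct = jawed_struct)
  expect_equal(t1$hypothesis, t3$hypothesis)
  expect_equal(t3$cost, t1$cost * 3)
})

test_that("identical hypotheses tie and sort stably by name", {
  hyps <- opsin_hypotheses()
  twins <- list(hyps$two_gene, hyps$two_gene)
  twins[[2]]$name <- "two_gene_copy"
  tab <- compare_hypotheses(jawed_pattern, twins, struct = jawed_struct)
  expect_equal(tab$cost[1], tab$cost[2])
  expect_equal(tab$hypothesis, c("two_gene", "two_gene_copy"))
})

test_that("the deferred RH-split model ranks first on the full pattern", {
  hyps <- opsin_hypotheses()
  tab <- compare_hypotheses(full_pattern, hyps, struct = full_struct)
  expect_equal(tab$hypothesis[1], "final_model")
  expect_lt(tab$cost[1], tab$cost[2])
  ## the winning scenario includes the jawless SWS1 translocation and
  ## replays exactly
  r <- min_cost_scenario(full_pattern, hyps$final_model, struct = full_struct)
  sc <- r$scenarios[[1]]
  tl <- sc$events[sc$events$kind == "TRANSLOCATION", ]
  expect_equal(nrow(tl), 1)
  expect_match(tl$edge, "^jawless")
  ro <- replay(hyps$final_model, sc$events, full_struct)
  expect_true(replay_matches(ro, sc$assignment, full_pattern, full_struct))
  ## co-optimal scenarios keep the SWS1 source ambiguity explicit
  expect_gte(r$n_cooptimal, 2)
})

test_that("scenario cost never exceeds the generating event count on truth", {
  ## the default simulated world: 19 scripted losses + 1 translocation
  ## explain the arrangements under the matching hypothesis
  hyps <- opsin_hypotheses()
  r <- min_cost_scenario(full_pattern, hyps$final_model, struct = full_struct)
  expect_lte(r$cost, 20)
})
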