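test_that("task checks match direct reachability on hand-built cases", {
  toy <- generate_toy_gem(2, seed = 91)
  pw <- attr(toy$model, "pathways")[[1]]
  reachable <- data.frame(task_id = "t1", description = "",
                          direction = c("in", "out"),
                          metabolite = c(pw$mets[1], pw$mets[2]),
                          lower = c(0, 0.05), upper = c(10, 10),
                          should_fail = FALSE)
  expect_equal(check_task(toy$model, reachable)$status, "pass")
  # no producing route: input from the other pathway only
  pw2 <- attr(toy$model, "pathways")[[2]]
  unreachable <- reachable
  unreachable$metabolite[1] <- pw2$mets[1]
  expect_equal(check_task(toy$model, unreachable)$status, "fail")
  # should_fail inverts the verdict
  unreachable$should_fail <- TRUE
  expect_equal(check_task(toy$model, unreachable)$status, "pass")
  # unresolvable metabolite: untestable, not a pass
  ghost <- reachable; ghost$metabolite[2] <- "no_such_met"
  res <- check_task(toy$model, ghost)
  expect_equal(res$status, "untestable")
  expect_true(is.na(res$feasible))
})

test_that("task verdicts equal the exhaustive LP-feasibility oracle", {
  toy <- generate_toy_gem(3, seed = 93)
  gen <- generate_tasks(toy$model, n_tasks = 10, n_infeasible = 4, seed = 7)
  res <- check_tasks(toy$model, gen$tasks)
  for (i in seq_len(nrow(res))) {
    tid <- res$task_id[i]
    task <- gen$tasks[gen$tasks$task_id == tid, , drop = FALSE]
    expect_equal(res$feasible[i], oracle_task_feasible(toy$model, task),
                 info = tid)
    expect_equal(res$feasible[i], unname(gen$truth$feasible[tid]), info = tid)
  }
})

test_that("task failure is monotone under reaction removal", {
  toy <- generate_toy_gem(2, seed = 95)
  gen <- generate_tasks(toy$model, n_tasks = 6, n_infeasible = 2, seed = 3)
  base_res <- check_tasks(toy$model, gen$tasks)
  set.seed(5)
  removable <- setdiff(model_reactions(toy$model), toy$model$objective)
  for (rep in 1:5) {
    sub <- remove_reactions(toy$model, sample(removable, 2))
    sub_res <- check_tasks(sub, gen$tasks)
    # anything failing on the full model still fails on the sub-model
    failed <- base_res$task_id[base_res$status == "fail"]
    expect_true(all(sub_res$status[sub_res$task_id %in% failed] == "fail"))
  }
})

test_that("gene_reactions distinguishes knockout coupling from listing", {
  m <- make_chain_model(gpr_chain = "g1 or g2")
  # isozyme within one rule: listed but not knockout-coupled
  expect_length(gene_reactions(m, "g1", mode = "knockout"), 0)
  expect_equal(gene_reactions(m, "g1", mode = "listing"), "R1")
  # sole-gene reaction: coupled in both modes
  m2 <- make_chain_model(gpr_chain = "g1")
  expect_equal(gene_reactions(m2, "g1", mode = "knockout"), "R1")
  expect_equal(gene_reactions(m2, "g1", mode = "listing"), "R1")
  # AND complex: coupled in both modes
  m3 <- make_chain_model(gpr_chain = "g1 and g2")
  expect_equal(gene_reactions(m3, "g1", mode = "knockout"), "R1")
  expect_equal(gene_reactions(m3, "g1", mode = "listing"), "R1")
  expect_error(gene_reactions(m, "ghost"), "ghost")
})

test_that("toxicity screen separates planted toxic from nontoxic candidates", {
  scen <- generate_screen_scenario(n_shared = 2, n_tumor_private = 2, seed = 29)
  report <- toxicity_screen(scen$healthy, scen$tasks,
                            candidates = scen$truth$essential_genes)
  toxic_found <- report$summary$gene[report$summary$toxic]
  expect_setequal(toxic_found, scen$truth$toxic_genes)
  # absent candidates flagged and nontoxic
  absent <- report$summary$gene[report$summary$absent]
  expect_true(all(absent %in% scen$truth$nontoxic_essential))
  expect_false(any(report$summary$toxic[report$summary$absent]))
})

test_that("screen is independent of candidate order", {
  scen <- generate_screen_scenario(seed = 31)
  cand <- scen$truth$essential_genes
  r1 <- toxicity_screen(scen$healthy, scen$tasks, cand)
  r2 <- toxicity_screen(scen$healthy, scen$tasks, rev(cand))
  s2 <- r2$summary[match(r1$summary$gene, r2$summary$gene), ]
  rownames(s2) <- NULL
  expect_identical(r1$summary, s2)
})

test_that("screen aborts on a baseline failure", {
  scen <- generate_screen_scenario(seed = 33)
  # an unsatisfiable demand makes the unperturbed model fail its battery
  extra <- data.frame(task_id = "task_bad", description = "",
                      direction = "out", metabolite = scen$healthy$mets$id[1],
                      lower = 100, upper = 200, should_fail = FALSE)
  expect_error(
    toxicity_screen(scen$healthy, rbind(scen$tasks, extra),
                    scen$truth$essential_genes),
    "baseline")
})

test_that("shortlist is the essential-and-nontoxic set ordered by growth effect", {
  scen <- generate_screen_scenario(seed = 35)
  ess <- essential_genes(scen$tumor)
  expect_setequal(ess$gene[ess$essential], scen$truth$essential_genes)
  report <- toxicity_screen(scen$healthy, scen$tasks, ess$gene[ess$essential])
  shortlist <- shortlist_targets(ess, report)
  expect_setequal(shortlist, scen$truth$nontoxic_essential)
  # all-toxic: empty shortlist
  all_toxic <- report
  all_toxic$summary$toxic <- TRUE
  expect_length(shortlist_targets(ess, all_toxic), 0)
  # disjoint essential/screened sets: mismatch error
  fake <- report
  fake$summary$gene <- paste0("zz_", fake$summary$gene)
  expect_error(shortlist_targets(ess, fake), "mismatch")
})

test_that("task tables round-trip through TSV", {
  scen <- generate_screen_scenario(seed = 37)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tasks(scen$tasks, path)
  back <- read_tasks(path)
  expect_equal(back$metabolite, scen$tasks$metabolite)
  expect_equal(back$lower, scen$tasks$lower)
  bad <- data.frame(task_id = "t", direction = "sideways",
                    metabolite = "m", lower = 0, upper = 1)
  expect_error(write_tasks(bad, path), "direction")
})
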