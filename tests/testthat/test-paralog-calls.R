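ann_row <- function(protein, reloc, dest, own, paralog) {
  tibble::tibble(protein = protein, relocalized = reloc, destination = dest,
                 own_wt_compartment = own, paralog_wt_compartment = paralog)
}

test_that("direction calls follow the compensation/dependency rules", {
  # abundance increase + relocalization into the paralog's compartment
  a <- ann_row("CUE4", TRUE, "cytoplasm", "ER", "cytoplasm")
  res <- call_direction(a, "increase")
  expect_equal(res$reloc_call, "compensation")
  expect_equal(res$abundance_call, "compensation")
  # relocalization away from both compartments, no abundance change
  h <- ann_row("HMS2", TRUE, "cytoplasm", "nucleus", "nucleus")
  res2 <- call_direction(h, "ns")
  expect_equal(res2$reloc_call, "dependency")
  expect_equal(res2$abundance_call, "none")
  # no relocalization, ns abundance
  n <- ann_row("QUIET", FALSE, NA_character_, "vacuole", "nucleus")
  res3 <- call_direction(n, "ns")
  expect_equal(unlist(res3[, c("reloc_call", "abundance_call")], use.names = FALSE),
               c("none", "none"))
  expect_equal(call_direction(n, "decrease")$abundance_call, "dependency")
  # invalid: destination equals the protein's own compartment
  bad <- ann_row("X", TRUE, "ER", "ER", "nucleus")
  expect_error(call_direction(bad, "ns"), "invalid annotation")
  expect_error(call_direction(ann_row("Y", TRUE, NA_character_, "ER", "nucleus"), "ns"),
               "destination")
})

test_that("pair summaries conserve counts", {
  flags <- tibble::tibble(protein = c("a1", "a2", "b1", "b2", "c1", "c2"),
                          flag_redistributed = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  pairs <- tibble::tibble(protein = flags$protein,
                          pair_id = rep(c("A", "B", "C"), each = 2))
  ps <- pair_summary(flags, pairs)
  expect_equal(unlist(ps$counts[, c("reciprocal", "single", "none")], use.names = FALSE),
               c(1L, 1L, 1L))
  expect_equal(ps$counts$reciprocal + ps$counts$single + ps$counts$none,
               ps$counts$n_pairs)
  expect_equal(2 * ps$counts$reciprocal + ps$counts$single,
               ps$counts$n_flagged_proteins)
  # all flags false
  none <- dplyr::mutate(flags, flag_redistributed = FALSE)
  expect_equal(unlist(pair_summary(none, pairs)$counts[, c("reciprocal", "single", "none")],
                      use.names = FALSE), c(0L, 0L, 3L))
  expect_error(pair_summary(flags, pairs[-1, ]), "unmapped")
  expect_error(pair_summary(flags, dplyr::bind_rows(pairs, pairs[1, ])),
               "more than one pair")
})

test_that("summaries are invariant to protein order", {
  set.seed(5)
  flags <- tibble::tibble(protein = sprintf("p%02d", 1:40),
                          flag_redistributed = runif(40) < 0.4)
  pairs <- tibble::tibble(protein = flags$protein,
                          pair_id = rep(sprintf("q%02d", 1:20), each = 2))
  s1 <- pair_summary(flags, pairs)$counts
  ord <- sample(40)
  s2 <- pair_summary(flags[ord, ], pairs)$counts
  expect_equal(s1, s2)
})

test_that("screen summary computes rounded percentages on the redistributed subset", {
  roster <- tibble::tibble(
    protein = sprintf("p%03d", 1:164),
    flag_redistributed = c(rep(TRUE, 32), rep(FALSE, 132)),
    relocalized = c(rep(TRUE, 9), rep(FALSE, 155)),
    abundance_class = c(rep("increase", 5), rep("ns", 11),
                        rep("decrease", 11), rep("ns", 137))
  )
  # 5 relocalized+abundance, 4 relocalized only, 11 abundance only
  s <- screen_summary(roster)
  expect_equal(s$pct_redistributed, 20)   # 32 / 164
  expect_equal(s$pct_relocalized, 28)     # 9 / 32
  expect_equal(s$pct_abundance_change, 50) # 16 / 32
  expect_equal(s$pct_both, 16)            # 5 / 32
  zero <- dplyr::mutate(roster, flag_redistributed = FALSE)
  s0 <- screen_summary(zero)
  expect_true(is.na(s0$pct_relocalized))
  expect_error(screen_summary(roster[0, ]), "empty roster")
})

test_that("roster filtering removes pairs wholesale", {
  pairs <- tibble::tibble(pair_id = sprintf("pr%02d", 1:91),
                          protein_a = sprintf("a%02d", 1:91),
                          protein_b = sprintf("b%02d", 1:91))
  out <- roster_filter(pairs, sprintf("pr%02d", 1:9))
  expect_equal(out$n_pairs, 82)
  expect_equal(out$n_proteins, 164)
  ident <- roster_filter(pairs, character())
  expect_equal(ident$pairs, pairs)
  small <- roster_filter(pairs[1:3, ], c("pr01", "pr03"))
  expect_equal(small$n_pairs, 1)
  expect_equal(small$n_proteins, 2)
  expect_error(roster_filter(pairs, "zz99"), "not in roster")
})

test_that("the summary network export links relocalized proteins to destinations", {
  ann <- dplyr::bind_rows(
    ann_row("A", TRUE, "cytoplasm", "ER", "cytoplasm"),
    ann_row("B", FALSE, NA_character_, "nucleus", "ER"))
  calls <- call_direction(ann, c("increase", "ns"))
  scores <- tibble::tibble(protein = c("A", "B"), score = c(2.1, 0.3),
                           flag_redistributed = c(TRUE, FALSE))
  net <- export_summary_network(calls, scores, ann)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$from, "A")
  expect_equal(net$edges$to, "cytoplasm")
  expect_equal(net$edges$reloc_call, "compensation")
  expect_setequal(net$nodes$node, c("A", "B", "cytoplasm"))
})

test_that("calls from generator truth reproduce the planted labels", {
  d <- screen_design(6, 2)
  tr <- sim_truth(d, seed = 12)
  partner <- setNames(d$proteins$partner, d$proteins$protein)
  ann <- tibble::tibble(
    protein = tr$protein,
    relocalized = tr$effect_relocalization > 0,
    destination = ifelse(tr$effect_relocalization > 0, tr$target_compartment, NA),
    own_wt_compartment = tr$wt_compartment,
    paralog_wt_compartment = tr$wt_compartment[match(partner[tr$protein], tr$protein)]
  )
  classes <- ifelse(tr$effect_abundance > 1, "increase",
                    ifelse(tr$effect_abundance < 1, "decrease", "ns"))
  calls <- call_direction(ann, classes)
  expect_equal(calls$abundance_call != "none", tr$effect_abundance != 1)
  expect_equal(calls$reloc_call != "none", tr$effect_relocalization > 0)
  # relocalization into the partner's compartment is always compensation
  into_partner <- ann$relocalized &
    ann$destination == ann$paralog_wt_compartment
  expect_true(all(calls$reloc_call[into_partner] == "compensation"))
})
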