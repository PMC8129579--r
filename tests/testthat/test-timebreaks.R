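test_that("time-break hand cases follow the 20% rule", {
  # TP = (0,1,1,1,1,1): TPbar = 5/6, |1-0|/TPbar = 1.2 > 0.2 -> breaks {x2}
  ab <- assign_time_breaks(c(0, 1, 1, 1, 1, 1))
  expect_equal(ab$tpbar, 5 / 6)
  expect_identical(ab$candidates, 2L)
  expect_identical(ab$main, 2L)

  # all-zero template is unclassifiable, not an error
  ab0 <- assign_time_breaks(rep(0, 6))
  expect_true(ab0$unclassifiable)
  expect_identical(ab0$candidates, integer(0))

  # late jump: breaks include x5 (jump 1.9 over a small pattern mean)
  ab2 <- assign_time_breaks(c(0, 0.1, 0.1, 0.1, 2, 2))
  expect_true(5L %in% ab2$candidates)
  expect_identical(ab2$main, 5L)
})

test_that("break assignment is scale invariant", {
  set.seed(55)
  for (i in 1:25) {
    tp <- c(0, rnorm(5))
    if (all(tp == 0)) next
    ab <- assign_time_breaks(tp)
    for (c_ in c(0.01, 3, 250)) {
      abc <- assign_time_breaks(c_ * tp)
      expect_identical(abc$candidates, ab$candidates)
      expect_identical(abc$main, ab$main)
    }
  }
})

test_that("the last stage is checked against the latest prior break", {
  # backward difference at x6 fails (0.15 < thr) but the change relative to
  # the x2 break passes: x6 becomes a candidate
  tp <- c(0, 1, 1.1, 1.1, 1.1, 1.25)
  tpbar <- mean(abs(tp))
  expect_lt(abs(tp[6] - tp[5]) / tpbar, 0.2)       # backward alone fails
  expect_gt(abs(tp[6] - tp[2]) / tpbar, 0.2)       # vs prior break passes
  ab <- assign_time_breaks(tp)
  expect_true(6L %in% ab$candidates)
  expect_identical(ab$main, 6L)                    # |1.25| > |1|
})

test_that("the main break maximizes distance from baseline, earlier on ties", {
  expect_identical(select_main_break(c(0, 1, 1, 1, 1, 1), 2L), 2L)
  # breaks {x2, x5}: |2| > |0.5| -> x5
  tp <- c(0, 0.5, 0.5, 0.5, 2, 2)
  ab <- assign_time_breaks(tp)
  expect_true(all(c(2L, 5L) %in% ab$candidates))
  expect_identical(ab$main, 5L)
  # symmetric magnitudes -> earlier stage
  expect_identical(select_main_break(c(0, 1.5, 0, 0, -1.5, 0), c(2L, 5L)), 2L)
  expect_error(select_main_break(c(0, 1), integer(0)), "unclassifiable")
})

test_that("MP sign classification at the break", {
  expect_identical(classify_mp_sign(c(0, 0, 0, 0, 1.3, 1.3), 5L), "positive")
  expect_identical(classify_mp_sign(c(0, 0, -0.4, -0.4, 0, 0), 3L), "negative")
  expect_identical(classify_mp_sign(c(0, 1, 0, 1, 1, 1), 3L), "unclassifiable")
})

test_that("main-pattern summarization groups by break and splits by sign", {
  tp_of <- function(id, template, members)
    list(term_id = id, tp_index = 1L, members = members, template = template)
  up <- c(0, 0, 2, 2, 2, 2)          # break x3, positive
  dn <- -up                          # break x3, negative
  late <- c(0, 0, 0, 0, 2, 2)        # break x5

  # one TP -> one MP equal to it
  mp1 <- summarize_main_patterns(list(tp_of("A", up, c("g1", "g2"))))
  expect_length(mp1$main_patterns, 1L)
  expect_equal(unname(mp1$main_patterns[[1]]$profile), up)
  expect_identical(mp1$main_patterns[[1]]$time_break, 3L)
  expect_identical(mp1$main_patterns[[1]]$sign, "positive")

  # two identical templates, same break -> a single MP with that profile
  mp2 <- summarize_main_patterns(list(tp_of("A", up, "g1"),
                                      tp_of("B", up, "g2")))
  expect_length(mp2$main_patterns, 1L)
  expect_setequal(mp2$main_patterns[[1]]$genes, c("g1", "g2"))

  # step-up and step-down sharing a break -> two MPs of opposite sign
  mp3 <- summarize_main_patterns(list(tp_of("A", up, "g1"),
                                      tp_of("B", dn, "g2")))
  expect_length(mp3$main_patterns, 2L)
  expect_setequal(vapply(mp3$main_patterns, `[[`, character(1), "sign"),
                  c("positive", "negative"))

  # different breaks never share an MP; flat TPs land in the
  # unclassified bucket
  mp4 <- summarize_main_patterns(list(tp_of("A", up, "g1"),
                                      tp_of("B", late, "g2"),
                                      tp_of("C", rep(0, 6), "g3")))
  expect_length(mp4$main_patterns, 2L)
  expect_identical(sort(vapply(mp4$main_patterns, `[[`, integer(1),
                               "time_break")), c(3L, 5L))
  expect_identical(mp4$unclassified_tps, "C.1")
  # every classified TP lands in exactly one MP
  tp_ids <- unlist(lapply(mp4$main_patterns, `[[`, "tp_ids"))
  expect_identical(sort(tp_ids), c("A.1", "B.1"))
})

test_that("breaks and signs of planted step patterns are recovered", {
  cfg <- strong_step_config()
  sim <- simulate_counts(cfg)
  ann <- simulate_annotations(cfg, sim$truth)
  lg <- log2_transform(filter_low_expression(sim$series))
  prof <- differential_profiles(lg)
  sel <- select_genes(prof, estimate_null(lg))
  fp <- find_patterns(sel, prof, ann$annotations, ann$hierarchy)
  leaf <- Filter(function(p) grepl("^T", p$term_id), fp$patterns)
  expect_gt(length(leaf), 10L)
  ok_brk <- ok_sgn <- logical(0)
  for (p in leaf) {
    mt <- majority_truth(p$members, sim$truth)
    if (is.null(mt)) next
    ab <- assign_time_breaks(p$template)
    if (is.na(ab$main)) next
    ok_brk <- c(ok_brk, ab$main == mt$break_stage)
    ok_sgn <- c(ok_sgn, (classify_mp_sign(p$template, ab$main) ==
                           "positive") == (mt$sign > 0))
  }
  expect_gte(mean(ok_brk), 0.9)
  expect_gte(mean(ok_sgn), 0.95)

  mp <- summarize_main_patterns(fp$patterns)
  expect_gt(length(mp$main_patterns), 2L)
  for (m in mp$main_patterns) {
    mt <- majority_truth(m$genes, sim$truth)
    if (is.null(mt)) next
    expect_identical((m$sign == "positive"), (mt$sign > 0))
  }
})
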