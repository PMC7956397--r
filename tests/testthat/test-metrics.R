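test_that("reference events validate coverage and contiguity", {
  ev <- reference_events(c("sedentary", "dynamic", "standing"),
                         c(0, 60, 120), c(60, 120, 180))
  expect_s3_class(ev, "reference_events")
  expect_error(reference_events(c("sedentary", "dynamic"), c(0, 50), c(60, 120)),
               "tile")
  expect_error(reference_events("sedentary", 10, 10), "duration")
  expect_error(reference_events("napping", 0, 10), "unknown activity")
})

test_that("windowizing the reference picks the majority label with a later-event tie-break", {
  # window fully inside one standing event
  ev <- reference_events("standing", 0, 8)
  expect_equal(windowize_reference(ev, 4, 2)$label, rep("standing", 2))

  # 2.5 s standing then 1.5 s dynamic inside a 4 s window
  ev <- reference_events(c("standing", "dynamic"), c(0, 2.5), c(2.5, 4))
  expect_equal(windowize_reference(ev, 4, 1)$label, "standing")

  # exact 2/2 tie goes to the later-starting (incoming) event
  ev <- reference_events(c("sedentary", "dynamic"), c(0, 2), c(2, 4))
  expect_equal(windowize_reference(ev, 4, 1)$label, "dynamic")

  # coverage gap is an error naming the span
  ev <- reference_events("standing", 0, 7.9)
  expect_error(windowize_reference(ev, 4, 2), "cover")

  # brute-force duration accumulation on random event tables
  set.seed(21)
  for (rep_i in 1:10) {
    n_ev <- sample(3:8, 1)
    durs <- runif(n_ev, 0.5, 9)
    labs <- random_labels(n_ev)
    ends <- cumsum(durs)
    ev <- reference_events(labs, c(0, ends[-n_ev]), ends)
    ws <- 2
    n_win <- floor(ends[n_ev] / ws)
    got <- windowize_reference(ev, ws, n_win)$label
    for (w in seq_len(n_win)) {
      s <- (w - 1) * ws; e <- w * ws
      acc <- c(sedentary = 0, standing = 0, dynamic = 0)
      best_onset <- c(sedentary = -Inf, standing = -Inf, dynamic = -Inf)
      for (k in seq_len(n_ev)) {
        ov <- min(ev$offset_s[k], e) - max(ev$onset_s[k], s)
        if (ov > 1e-12) {
          acc[ev$label[k]] <- acc[ev$label[k]] + ov
          best_onset[ev$label[k]] <- max(best_onset[ev$label[k]], ev$onset_s[k])
        }
      }
      top <- names(acc)[acc >= max(acc) - 1e-9]
      want <- top[which.max(best_onset[top])]
      expect_equal(got[w], want)
    }
  }
})

test_that("confusion counts agree with per-element counting", {
  # worked example
  cm <- confusion_counts(c("dynamic", "dynamic", "standing", "sedentary"),
                         c("dynamic", "standing", "standing", "sedentary"),
                         "dynamic")
  expect_equal(list(cm$tp, cm$fp, cm$tn, cm$fn), list(1L, 1L, 2L, 0L))

  # identical series have no errors
  set.seed(22)
  v <- random_labels(50)
  cm <- confusion_counts(v, v, "standing")
  expect_equal(cm$fp + cm$fn, 0L)

  # transition target compares boundary flags
  cm <- confusion_counts(c("sedentary", "standing"), c("sedentary", "sedentary"),
                         "transition")
  expect_equal(list(cm$tp, cm$fp, cm$tn, cm$fn), list(0L, 1L, 0L, 0L))

  expect_error(confusion_counts(random_labels(4), random_labels(5), "dynamic"),
               "lengths differ")

  # random pairs against the brute-force oracle, all targets
  for (i in 1:30) {
    a <- random_labels(60); r <- random_labels(60)
    for (target in ACTIVITY_LEVELS) {
      want <- oracle_confusion(a, r, target)
      got <- confusion_counts(a, r, target)
      expect_equal(list(got$tp, got$fp, got$tn, got$fn),
                   list(want$tp, want$fp, want$tn, want$fn))
    }
    want <- oracle_confusion(oracle_transition_flags(a),
                             oracle_transition_flags(r), 1L)
    got <- confusion_counts(a, r, "transition")
    expect_equal(list(got$tp, got$fp, got$tn, got$fn),
                 list(want$tp, want$fp, want$tn, want$fn))
  }
})

test_that("one-vs-rest confusions pool consistently over the three classes", {
  set.seed(23)
  a <- random_labels(200); r <- random_labels(200)
  cms <- lapply(ACTIVITY_LEVELS, function(cl) confusion_counts(a, r, cl))
  tp <- sum(vapply(cms, `[[`, 0, "tp")); fn <- sum(vapply(cms, `[[`, 0, "fn"))
  fp <- sum(vapply(cms, `[[`, 0, "fp")); tn <- sum(vapply(cms, `[[`, 0, "tn"))
  expect_equal(tp + fn, 200)                     # each window once as reference
  expect_equal(tp, sum(a == r))                  # pooled TP = agreements
  # pooled (micro-averaged) accuracy equals direct computation
  expect_equal(100 * (tp + tn) / (tp + fp + tn + fn),
               sens_spec_acc(list(tp = tp, fp = fp, tn = tn, fn = fn))[["accuracy_pct"]])
})

test_that("sensitivity/specificity/accuracy follow the standard forms", {
  ssa <- sens_spec_acc(list(tp = 9, fn = 1, tn = 5, fp = 5))
  expect_equal(unname(ssa), c(90, 50, 70))

  ssa <- sens_spec_acc(list(tp = 10, fn = 0, tn = 20, fp = 0))
  expect_equal(unname(ssa), c(100, 100, 100))

  # undefined ratios are NA, not errors
  ssa <- sens_spec_acc(list(tp = 0, fn = 0, tn = 5, fp = 5))
  expect_true(is.na(ssa[["sensitivity_pct"]]))
  expect_equal(ssa[["specificity_pct"]], 50)

  expect_error(sens_spec_acc(list(tp = 0, fn = 0, tn = 0, fp = 0)), "zero")

  set.seed(24)
  for (i in 1:20) {
    a <- random_labels(200); r <- random_labels(200)
    cm <- oracle_confusion(a, r, "dynamic")
    ssa <- sens_spec_acc(confusion_counts(a, r, "dynamic"))
    expect_equal(ssa[["sensitivity_pct"]], 100 * cm$tp / (cm$tp + cm$fn))
    expect_equal(ssa[["specificity_pct"]], 100 * cm$tn / (cm$tn + cm$fp))
    expect_equal(ssa[["accuracy_pct"]], 100 * (cm$tp + cm$tn) / 200)
  }
})

test_that("percentage error carries the overestimation sign convention", {
  expect_equal(unname(percentage_error(100, 120)), c(-20, 20))
  expect_equal(unname(percentage_error(75, 75)), c(0, 0))
  expect_equal(percentage_error(1, 3)[["pe_pct"]], -200)
  expect_true(all(is.na(percentage_error(0, 10))))
})

test_that("total error is time-weighted and telescopes on a shared grid", {
  expect_equal(unname(total_error(c(100, 50, 50), c(110, 50, 40))), c(0, 10))

  set.seed(25)
  for (i in 1:20) {
    a <- random_labels(120); r <- random_labels(120)
    ws <- 4
    rt <- vapply(ACTIVITY_LEVELS, function(cl) sum(r == cl) * ws, 0)
    at <- vapply(ACTIVITY_LEVELS, function(cl) sum(a == cl) * ws, 0)
    te <- total_error(rt, at)
    expect_equal(te[["pe_pct"]], 0)
    # oracle: per-class absolute time differences summed directly
    want <- sum(abs(rt - at)) / sum(rt) * 100
    expect_equal(te[["ape_pct"]], want)
    # and total APE is bounded by twice the misclassified time
    expect_lte(te[["ape_pct"]],
               2 * sum(a != r) * ws / sum(rt) * 100 + 1e-12)
  }
})

test_that("subject report assembles all metric families coherently", {
  set.seed(26)
  ws <- 4
  r <- c("sedentary", "sedentary", "sedentary", "dynamic", "dynamic",
         "standing", "sedentary", "sedentary")
  ev <- events_from_labels(r, ws)

  # perfect agreement
  rep0 <- subject_report(r, ev, ws, subject_id = "p")
  expect_equal(rep0$activity,
               c("sedentary", "standing", "dynamic", "total", "transitions"))
  expect_true(all(rep0$sensitivity_pct == 100))
  expect_true(all(rep0$specificity_pct == 100))
  expect_true(all(rep0$accuracy_pct == 100))
  expect_true(all(rep0$pe_pct == 0))

  # flipping a mid-run sedentary window to standing splits the sedentary
  # bout and fabricates an extra transition
  a <- r
  a[2] <- "standing"
  rep1 <- subject_report(a, ev, ws)
  tr <- rep1[rep1$activity == "transitions", ]
  expect_equal(tr$fp, 1)
  expect_equal(tr$tp, 1)
  expect_equal(tr$reference_count, 1)
  expect_equal(tr$algorithm_count, 2)
  expect_equal(tr$pe_pct, -100)   # overestimated transitions

  # invariant ape = |pe| per activity; total ape >= |total pe|
  for (i in 1:10) {
    a <- random_labels(40)
    ev <- events_from_labels(random_labels(40), ws)
    rp <- subject_report(a, ev, ws)
    act <- rp$activity %in% ACTIVITY_LEVELS & !is.na(rp$pe_pct)
    expect_equal(rp$ape_pct[act], abs(rp$pe_pct[act]))
    expect_gte(rp$ape_pct[rp$activity == "total"] + 1e-12,
               abs(rp$pe_pct[rp$activity == "total"]))
  }
})

test_that("metrics are invariant to an identical window permutation", {
  set.seed(27)
  a <- random_labels(100); r <- random_labels(100)
  perm <- sample(100)
  for (target in c(ACTIVITY_LEVELS)) {
    c1 <- confusion_counts(a, r, target)
    c2 <- confusion_counts(a[perm], r[perm], target)
    expect_equal(list(c1$tp, c1$fp, c1$tn, c1$fn),
                 list(c2$tp, c2$fp, c2$tn, c2$fn))
  }
})

test_that("cohort summary aggregates with type-7 quartiles and drops undefined values", {
  ws <- 4
  set.seed(28)
  reports <- lapply(1:7, function(i) {
    r <- random_labels(60)
    a <- r
    flip <- sample(60, 8)
    a[flip] <- random_labels(8)
    subject_report(a, events_from_labels(r, ws), ws,
                   subject_id = sprintf("s%02d", i))
  })
  cs <- cohort_summary(reports)

  all_rep <- do.call(rbind, reports)
  for (act in c("sedentary", "total", "transitions")) {
    for (m in c("sensitivity_pct", "ape_pct")) {
      vals <- all_rep[[m]][all_rep$activity == act]
      vals <- vals[!is.na(vals)]
      row <- cs[cs$activity == act & cs$metric == m, ]
      expect_equal(row$n_subjects, length(vals))
      if (length(vals) > 0) {
        expect_equal(row$median, oracle_quantile7(vals, 0.5))
        expect_equal(row$q1, oracle_quantile7(vals, 0.25))
        expect_equal(row$q3, oracle_quantile7(vals, 0.75))
        expect_true(row$q1 <= row$median && row$median <= row$q3)
      }
    }
  }

  # single report: median = q1 = q3
  cs1 <- cohort_summary(reports[[1]])
  defined <- !is.na(cs1$median)
  expect_equal(cs1$median[defined], cs1$q1[defined])
  expect_equal(cs1$median[defined], cs1$q3[defined])

  # {10, 20, 30} -> median 20 and acceptability limits applied
  fake <- reports[1:3]
  for (i in 1:3) {
    fake[[i]]$sensitivity_pct <- c(10, 20, 30)[i]
    fake[[i]]$ape_pct <- c(10, 20, 30)[i]
  }
  csf <- cohort_summary(fake)
  sed_sens <- csf[csf$activity == "sedentary" & csf$metric == "sensitivity_pct", ]
  expect_equal(sed_sens$median, 20)
  expect_false(sed_sens$acceptable)    # below the 80% limit
  sed_ape <- csf[csf$activity == "sedentary" & csf$metric == "ape_pct", ]
  expect_false(sed_ape$acceptable)     # APE must be below 10%

  expect_error(cohort_summary(list()), "no reports")
})
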