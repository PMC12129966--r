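test_that("Naranjo scores sum the packaged per-question points", {
  all_unknown <- rep("unknown", 10)
  expect_equal(naranjo_score(all_unknown), 0)
  # yes to Q1-Q4: 1 + 2 + 1 + 2 = 6
  a <- all_unknown; a[1:4] <- "yes"
  expect_equal(naranjo_score(a), 6)
  # no to Q2, Q4, Q5: -1 - 1 + 2 = 0 (a negative answer on alternative
  # causes adds evidence for the drug)
  a <- all_unknown; a[c(2, 4, 5)] <- "no"
  expect_equal(naranjo_score(a), 0)
  # all yes: 1+2+1+2-1-1+1+1+1+1 = 8
  expect_equal(naranjo_score(rep("yes", 10)), 8)
  expect_error(naranjo_score(rep("yes", 9)), "exactly 10")
  expect_error(naranjo_score(c(rep("yes", 9), "maybe")), "yes")
})

test_that("Naranjo category bands break exactly at 0/1, 4/5, 8/9", {
  scores <- -4:13
  cats <- naranjo_category(scores)
  oracle <- ifelse(scores >= 9, "definite",
                   ifelse(scores >= 5, "probable",
                          ifelse(scores >= 1, "possible", "doubtful")))
  expect_equal(cats, oracle)
  # piecewise-constant: category changes only at the three breakpoints
  changes <- scores[which(cats[-1] != cats[-length(cats)]) + 1L]
  expect_equal(changes, c(1, 5, 9))
})

test_that("WHO-UMC decision table maps fact combinations deterministically", {
  expect_equal(who_causality("yes", "present"), "possible")
  expect_equal(who_causality("yes", "excluded", dechallenge = "positive"),
               "probable")
  expect_equal(who_causality("yes", "excluded", dechallenge = "positive",
                             rechallenge = "positive"), "certain")
  expect_equal(who_causality("no", "present"), "unlikely")
  expect_equal(who_causality("unknown", "unknown"), "conditional_unclassified")
  expect_equal(who_causality("yes", "present", data_sufficient = FALSE),
               "unassessable_unclassifiable")
  expect_error(who_causality("yes", "excluded", rechallenge = "positive",
                             data_sufficient = FALSE), "contradictory")
})

test_that("adding supporting evidence never weakens the WHO-UMC category", {
  rank <- c(unassessable_unclassifiable = 0, conditional_unclassified = 1,
            unlikely = 1, possible = 2, probable = 3, certain = 4)
  base <- rank[[who_causality("yes", "present")]]
  better_alt <- rank[[who_causality("yes", "excluded")]]
  expect_gte(better_alt, base)
  with_de <- rank[[who_causality("yes", "excluded", dechallenge = "positive")]]
  expect_gte(with_de, better_alt)
  with_re <- rank[[who_causality("yes", "excluded", dechallenge = "positive",
                                 rechallenge = "positive")]]
  expect_gte(with_re, with_de)
})

test_that("severity and mechanism classification", {
  expect_equal(classify_severity(FALSE, FALSE, FALSE), "mild")
  expect_equal(classify_severity(TRUE, TRUE, FALSE), "moderate")
  expect_equal(classify_severity(FALSE, TRUE, FALSE), "moderate")
  expect_equal(classify_severity(TRUE, TRUE, TRUE), "severe")
  expect_equal(classify_mechanism(TRUE, TRUE), "A")
  expect_equal(classify_mechanism(FALSE, FALSE), "B")
  expect_equal(classify_mechanism(TRUE, FALSE), "B")
})

test_that("dual-review merge: agreement, tiebreak, divergence error", {
  a <- list(reviewer_id = "R1", patient_id = "P1", drug_name = "Heparin",
            reaction = "Epistaxis", severity = "severe",
            naranjo_category = "possible")
  b <- a; b$reviewer_id <- "R2"
  expect_equal(merge_reviews(a, b)$severity, "severe")
  # symmetric when the reviews agree
  expect_equal(merge_reviews(a, b)[order(names(merge_reviews(a, b)))],
               merge_reviews(b, a)[order(names(merge_reviews(b, a)))])
  b2 <- b; b2$severity <- "moderate"
  third <- a; third$severity <- "moderate"
  expect_equal(merge_reviews(a, b2, third)$severity, "moderate")
  b3 <- b; b3$naranjo_category <- "probable"
  expect_error(merge_reviews(a, b3), "naranjo_category")
  a2 <- a; a2$patient_id <- "P2"
  expect_error(merge_reviews(a2, b), "same ADR")
})

test_that("ATC lookup covers the packaged dictionary and warns on unknowns", {
  expect_equal(atc_lookup("Regular insulin"), "A10AB01")
  expect_equal(atc_lookup("Enoxaparin"), "B01AB05")
  expect_equal(atc_lookup("insulin"), "A10AB01")       # synonym
  expect_equal(atc_lookup("ENOXAPARIN"), "B01AB05")    # case-insensitive
  expect_warning(code <- atc_lookup("unknowndrug"), "unknowndrug")
  expect_equal(code, "")
  # every code in the dictionary is a well-formed 7-character ATC code
  dict <- icutrigger:::atc_dictionary()
  expect_true(all(grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", dict$atc_code)))
})

test_that("machine adjudication reproduces the embedded ground truth", {
  sim <- generate_cohort(default_config(n_patients = 120), seed = 21)
  hits <- scan_cohort(sim$cohort)
  adrs <- adjudicate_cohort(sim$cohort, hits)
  gt <- sim$ground_truth
  expect_equal(nrow(adrs), nrow(gt))
  m <- merge(adrs, gt, by = c("patient_id", "drug_name", "reaction",
                              "onset_day"), suffixes = c(".adj", ".gt"))
  expect_equal(nrow(m), nrow(gt))
  expect_equal(m$severity.adj, m$severity.gt)
  expect_equal(m$mechanism.adj, m$mechanism.gt)
  expect_equal(m$naranjo_score.adj, m$naranjo_score.gt)
  expect_equal(m$naranjo_category.adj, m$naranjo_category.gt)
  expect_equal(m$who_causality.adj, m$who_causality.gt)
  expect_equal(m$atc_code.adj, m$atc_code.gt)
})
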