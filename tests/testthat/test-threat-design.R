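test_that("enumerate_combinations orders labels canonically", {
  labs <- enumerate_combinations(list("exploitation", "disease",
                                      c("exploitation", "disease")))
  expect_equal(labs, c("disease", "exploitation", "disease.exploitation"))
  # sub-combinations of observed multi-threat sets are added
  labs2 <- enumerate_combinations(list(c("pollution", "invasive",
                                         "climate_change")))
  expect_equal(labs2, c(
    "climate_change", "invasive", "pollution",
    "climate_change.invasive", "climate_change.pollution",
    "invasive.pollution", "climate_change.invasive.pollution"
  ))
  # full enumeration: C(6,1)+C(6,2)+C(6,3) = 41
  expect_length(enumerate_combinations(list(), observed_only = FALSE), 41)
  expect_error(enumerate_combinations(list(threat_categories()[1:4])),
               "max_order")
  expect_error(enumerate_combinations(list("dragons")), "unknown")
})

test_that("count_fixed_effects matches the published coefficient counts", {
  expect_identical(count_fixed_effects(36), 74L)
  expect_identical(count_fixed_effects(36, 5), 370L)
  expect_identical(count_fixed_effects(character(0)), 2L)
  expect_error(count_fixed_effects(36, 0), "crossing_levels")
})

design_row <- function(d, i = 1) d$matrix[i, ]

two_threat_prep <- function() {
  tibble::tibble(
    threats = list(c("disease", "exploitation"), character(0)),
    centered_year = c(1, 2)
  )
}

test_that("build_design reproduces the worked exploitation+disease row", {
  labels <- enumerate_combinations(
    list(c("disease", "exploitation", "pollution")))
  d <- build_design(two_threat_prep(), labels)
  r <- design_row(d)
  expect_equal(unname(r[c("exploitation", "disease", "pollution",
                          "disease.exploitation", "exploitation.pollution",
                          "disease.pollution",
                          "disease.exploitation.pollution")]),
               c(1, 1, 0, 1, 0, 0, 0))
  # year twins follow the indicator times centred year
  expect_equal(unname(r["disease.exploitation:year"]), 1)
  expect_equal(unname(r["intercept"]), 1)
  # no-threat row has all combination indicators zero
  r2 <- design_row(d, 2)
  expect_true(all(r2[labels] == 0))
  expect_equal(unname(r2["year"]), 2)
  # column count follows 2 + 2 * labels
  expect_equal(ncol(d$matrix), count_fixed_effects(labels))
})

test_that("build_design errors on an uncovered threat set", {
  expect_error(build_design(two_threat_prep(), labels = c("disease")),
               "no covering label")
})

test_that("build_design agrees with a brute-force enumerator on 4 threats", {
  cats <- c("climate_change", "disease", "exploitation", "habitat_loss")
  sets <- list(character(0))
  for (k in 1:3) {
    sets <- c(sets, utils::combn(cats, k, identity, simplify = FALSE))
  }
  prep <- tibble::tibble(threats = sets,
                         centered_year = seq(-7, 7)[seq_along(sets)])
  labels <- enumerate_combinations(sets)
  d <- build_design(prep, labels)
  # brute force: direct set membership and elementwise products
  brute <- matrix(0, nrow(prep), 2 + 2 * length(labels))
  colnames(brute) <- colnames(d$matrix)
  brute[, "intercept"] <- 1
  brute[, "year"] <- prep$centered_year
  for (i in seq_len(nrow(prep))) {
    for (lab in labels) {
      toks <- strsplit(lab, ".", fixed = TRUE)[[1]]
      ind <- prod(as.numeric(toks %in% prep$threats[[i]]))
      brute[i, lab] <- ind
      brute[i, paste0(lab, ":year")] <- ind * prep$centered_year[i]
    }
  }
  expect_identical(d$matrix, brute)
  # interaction indicators equal the product of their singles
  for (lab in labels[lengths(strsplit(labels, ".", fixed = TRUE)) > 1]) {
    toks <- strsplit(lab, ".", fixed = TRUE)[[1]]
    expect_equal(d$matrix[, lab],
                 apply(d$matrix[, toks, drop = FALSE], 1, prod))
  }
})

test_that("switch_interactions toggles a column and restores it exactly", {
  labels <- enumerate_combinations(
    list(c("disease", "exploitation", "pollution")))
  d <- build_design(two_threat_prep(), labels)
  off <- switch_interactions(d, "disease.exploitation", "off")
  expect_true(all(off$matrix[, "disease.exploitation"] == 0))
  expect_true(all(off$matrix[, "disease.exploitation:year"] == 0))
  # additive prediction keeps the singles on
  expect_equal(unname(off$matrix[1, c("disease", "exploitation")]),
               c(1, 1))
  changed <- colnames(d$matrix)[apply(d$matrix != off$matrix, 2, any)]
  expect_setequal(changed, c("disease.exploitation",
                             "disease.exploitation:year"))
  on <- switch_interactions(off, "disease.exploitation", "on")
  expect_identical(on$matrix, d$matrix)
  # toggling a combo absent from every row changes nothing
  off2 <- switch_interactions(d, "disease.pollution", "off")
  expect_identical(off2$matrix, d$matrix)
  expect_error(switch_interactions(d, "disease.invasive", "off"),
               "unknown")
  expect_error(switch_interactions(d, "disease", "off"),
               "not an interaction")
})

test_that("remove_threat zeroes every column containing the threat", {
  labels <- enumerate_combinations(
    list(c("disease", "exploitation", "pollution")))
  d <- build_design(two_threat_prep(), labels)
  r <- remove_threat(d, "exploitation")
  row <- r$matrix[1, ]
  # exploitation removed, disease remains, interaction also removed
  expect_equal(unname(row[c("exploitation", "disease",
                            "disease.exploitation")]), c(0, 1, 0))
  # idempotent and commutative
  expect_identical(remove_threat(r, "exploitation")$matrix, r$matrix)
  ab <- remove_threat(remove_threat(d, "disease"), "exploitation")
  ba <- remove_threat(remove_threat(d, "exploitation"), "disease")
  expect_identical(ab$matrix, ba$matrix)
  # removing a threat absent everywhere changes nothing
  expect_identical(remove_threat(d, "invasive")$matrix, d$matrix)
  # removing all six zeroes every combination column
  all_gone <- Reduce(remove_threat, threat_categories(), d)
  expect_true(all(all_gone$matrix[, labels] == 0))
  expect_error(remove_threat(d, "asteroids"), "unknown")
})
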