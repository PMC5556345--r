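test_that("built-in banks load with the documented structure", {
  vfq25 <- load_instrument_bank("vfq25")
  expect_equal(nrow(vfq25$items), 25)
  expect_true(all(c("VF2", "VF15C", "VF16A", "VF25") %in% vfq25$items$code))
  expect_false("VH1" %in% vfq25$items$code)
  expect_equal(nrow(vfq25$subscales), 11)
  expect_setequal(unlist(vfq25$subscales$item_codes), vfq25$items$code)

  vfq28r <- load_instrument_bank("vfq28r")
  expect_equal(nrow(vfq28r$items), 28)
  expect_equal(nrow(vfq28r$subscales), 2)
  sizes <- sort(vapply(vfq28r$subscales$item_codes, length, integer(1)))
  expect_equal(sizes, c(9L, 19L))
  # domain partition is disjoint and exhaustive
  all_codes <- unlist(vfq28r$subscales$item_codes)
  expect_equal(sort(all_codes), sort(vfq28r$items$code))
  expect_equal(anyDuplicated(all_codes), 0L)

  vfq25a <- load_instrument_bank("vfq25a")
  expect_equal(nrow(vfq25a$items), 31)
})

test_that("malformed banks are rejected with the offending field named", {
  raw <- jsonlite::fromJSON(system.file("extdata", "banks", "vfq25.json",
                                        package = "vfqr"),
                            simplifyVector = FALSE)
  dup <- raw
  dup$items[[2]]$code <- dup$items[[1]]$code
  expect_error(vfqr:::parse_instrument_bank(dup), "duplicate item code")

  badcat <- raw
  badcat$items[[1]]$n_categories <- 9L
  badcat$items[[1]]$category_labels <- as.list(letters[1:9])
  expect_error(vfqr:::parse_instrument_bank(badcat), "n_categories")

  badsub <- raw
  badsub$subscales[[1]]$item_codes <- list("NOPE")
  expect_error(vfqr:::parse_instrument_bank(badsub), "NOPE")

  expect_error(load_instrument_bank("no_such_bank"), "Unknown instrument bank")
})

test_that("classical item recode maps categories linearly onto 0-100", {
  vfq25 <- load_instrument_bank("vfq25")
  items <- vfq25$items
  # best response on any item -> 100; worst -> 0; monotone throughout
  for (i in seq_len(nrow(items))) {
    it <- items[i, ]
    n_valid <- it$n_categories - as.integer(!is.na(it$stopped_other_reasons_category))
    scores <- classical_item_recode(seq_len(n_valid), it)
    if (it$reverse_scored) scores <- rev(scores)
    expect_equal(scores[1], 100)
    expect_equal(scores[n_valid], 0)
    expect_true(all(diff(scores) < 0))
  }
  # middle category of a 5-point scale -> 50 (equal spacing)
  vf4 <- items[items$code == "VF4", ]
  expect_equal(classical_item_recode(3L, vf4), 50)
  expect_equal(classical_item_recode(1:5, vf4), c(100, 75, 50, 25, 0))
  # 6-level quality item: interior spacing of 20
  vf2 <- items[items$code == "VF2", ]
  expect_equal(classical_item_recode(1:6, vf2), c(100, 80, 60, 40, 20, 0))
  # stopped-for-other-reasons level is missing
  vf5 <- items[items$code == "VF5", ]
  expect_true(is.na(classical_item_recode(6L, vf5)))
  expect_equal(classical_item_recode(1:5, vf5), c(100, 75, 50, 25, 0))
  expect_error(classical_item_recode(7L, vf5), "Invalid category")
})

test_that("sub-domain scores are means with the half-answered rule", {
  vfq25 <- load_instrument_bank("vfq25")
  best <- uniform_response(vfq25)
  sub <- classical_subscale_scores(best, vfq25)
  expect_equal(nrow(sub), 11)
  expect_true(all(sub$score == 100))

  # two-item sub-domain (role_difficulties: VF17, VF18) with 100 and 50
  d <- best
  d$VF17 <- 5L  # reverse-coded: best
  d$VF18 <- 3L  # middle -> 50
  sub2 <- classical_subscale_scores(d, vfq25)
  expect_equal(sub2$score[sub2$subscale == "role_difficulties"], 75)

  # one-item sub-domain equals the item score
  d$VF2 <- 3L
  sub3 <- classical_subscale_scores(d, vfq25)
  expect_equal(sub3$score[sub3$subscale == "general_vision"], 60)

  # fewer than half answered -> sub-domain missing (mental_health has 4 items)
  d2 <- best
  d2$VF3 <- NA_integer_; d2$VF21 <- NA_integer_; d2$VF22 <- NA_integer_
  sub4 <- classical_subscale_scores(d2, vfq25)
  mh <- sub4[sub4$subscale == "mental_health", ]
  expect_true(is.na(mh$score))
  expect_equal(mh$n_answered, 1L)
  # exactly half answered -> kept
  d3 <- best
  d3$VF3 <- NA_integer_; d3$VF21 <- NA_integer_
  sub5 <- classical_subscale_scores(d3, vfq25)
  expect_false(is.na(sub5$score[sub5$subscale == "mental_health"]))
})

test_that("composite averages exactly 11 sub-domain scores", {
  vfq25 <- load_instrument_bank("vfq25")
  best <- uniform_response(vfq25)
  worst <- uniform_response(vfq25, "worst")
  sub <- classical_subscale_scores(dplyr::bind_rows(best, worst), vfq25)
  comp <- classical_composite(sub)
  expect_equal(comp$composite[comp$person_id == "best"], 100)
  expect_equal(comp$composite[comp$person_id == "worst"], 0)
  expect_equal(comp$n_subscales, c(11L, 11L))

  # 6 zeros and 5 hundreds -> 500/11
  fake <- tibble::tibble(person_id = "p",
                         subscale = sprintf("s%02d", 1:11),
                         score = c(rep(0, 6), rep(100, 5)),
                         n_answered = 1L, n_items = 1L)
  expect_equal(classical_composite(fake)$composite, 500 / 11, tolerance = 1e-12)
  # wrong sub-domain count is an error
  expect_error(classical_composite(fake[1:10, ]), "exactly 11")
})

test_that("VFQ-28-R construction drops, adds, collapses and recodes as specified", {
  dat <- simulate_vfq25a(n_persons = 200, seed = 42, missing_rate = 0.03,
                         stopped_rate = 0.05)
  out <- build_vfq28r(dat)
  resp <- out$responses
  instr <- out$instrument
  expect_equal(ncol(resp) - 1L, 28L)
  expect_false(any(c("VF2", "VF3", "VF4") %in% names(resp)))
  expect_true(all(paste0("VFA", 3:8) %in% names(resp)))
  sizes <- vapply(instr$subscales$item_codes, length, integer(1))
  expect_equal(sort(sizes), c(9L, 19L))

  # nine items level-collapsed: 4 categories in the output definitions
  collapsed <- c("VF12", "VF13", "VF14", "VF15C", "VF16", "VF16A",
                 "VF18", "VF19", "VF25")
  expect_equal(instr$items$n_categories[match(collapsed, instr$items$code)],
               rep(4L, 9))

  # 'not sure' (category 3) on VF20-VF24 recoded missing, others renumbered
  for (code in paste0("VF", 20:24)) {
    was3 <- which(!is.na(dat[[code]]) & dat[[code]] == 3)
    expect_true(all(is.na(resp[[code]][was3])))
    expect_equal(resp[[code]][dat[[code]] == 5 & !is.na(dat[[code]])],
                 rep(4L, sum(dat[[code]] == 5, na.rm = TRUE)))
  }
  # collapse direction: categories 4 and 5 of VF12 merge into 4
  src <- dat$VF12
  expect_true(all(resp$VF12[!is.na(src) & src %in% c(4, 5)] == 4L))
  # stopped-for-other-reasons became missing
  expect_true(all(is.na(resp$VF12[!is.na(src) & src == 6])))

  # purity: input untouched, construction deterministic
  dat2 <- simulate_vfq25a(n_persons = 200, seed = 42, missing_rate = 0.03,
                          stopped_rate = 0.05)
  expect_identical(dat, dat2)
  out2 <- build_vfq28r(dat2)
  expect_identical(out$responses, out2$responses)

  # missing source columns named in the error
  expect_error(build_vfq28r(dat[setdiff(names(dat), "VFA5")]), "VFA5")
})

test_that("apply_rescore conserves responses and validates maps", {
  vfq25a <- load_instrument_bank("vfq25a")
  vfq28r <- load_instrument_bank("vfq28r")
  dat <- simulate_vfq25a(n_persons = 150, seed = 9, missing_rate = 0.05,
                         stopped_rate = 0.05)

  # identity (empty) rules leave data unchanged
  ident <- vfqr:::parse_rescore_rules(NULL)
  expect_identical(apply_rescore(dat, vfq25a, ident)$responses, dat)

  # conservation: output non-missing + newly-missing = input non-missing
  # over retained items
  res <- apply_rescore(dat, vfq25a, vfq28r$rescore_rules)
  retained <- res$items$code
  n_in <- sum(!is.na(dat[retained]))
  n_out <- sum(!is.na(res$responses[retained]))
  newly_missing <- sum(!is.na(dat[retained]) & is.na(res$responses[retained]))
  expect_equal(n_out + newly_missing, n_in)
  # every newly-missing cell was a recoded category (6 or a 'not sure' 3)
  for (code in retained) {
    idx <- which(!is.na(dat[[code]]) & is.na(res$responses[[code]]))
    if (length(idx)) {
      expect_true(all(dat[[code]][idx] %in%
                        c(6L, if (code %in% paste0("VF", 20:24)) 3L)))
    }
  }

  # collapse to 3 categories via the documented map shape
  r <- tibble::tibble(item_code = "VF15C", action = "collapse_levels",
                      collapse_map = list(c(1L, 2L, 2L, 3L, 3L)),
                      missing_categories = list(NULL))
  out <- apply_rescore(dat, vfq25a, r)
  expect_equal(out$items$n_categories[out$items$code == "VF15C"], 3L)
  expect_lte(max(out$responses$VF15C, na.rm = TRUE), 3L)

  # non-contiguous or non-monotone maps are configuration errors
  bad1 <- r; bad1$collapse_map <- list(c(1L, 3L, 3L, 4L, 5L))
  expect_error(apply_rescore(dat, vfq25a, bad1), "contiguous")
  bad2 <- r; bad2$collapse_map <- list(c(2L, 1L, 2L, 3L, 3L))
  expect_error(apply_rescore(dat, vfq25a, bad2), "order-preserving")
})

test_that("response validation names the offending cell", {
  vfq25 <- load_instrument_bank("vfq25")
  best <- uniform_response(vfq25)
  bad <- best
  bad$VF4 <- 7L
  expect_error(validate_responses(bad, vfq25), "VF4.*row 1.*7")
  expect_silent(validate_responses(best, vfq25))
})

test_that("PCM score conversion flips reverse-coded items and drops stopped level", {
  vfq25 <- load_instrument_bank("vfq25")
  best <- uniform_response(vfq25)
  worst <- uniform_response(vfq25, "worst")
  sb <- vfq_scores(best, vfq25)
  sw <- vfq_scores(worst, vfq25)
  m <- vfqr:::n_valid_categories(vfq25$items) - 1L
  expect_equal(unlist(sb[1, vfq25$items$code]), setNames(m, vfq25$items$code))
  expect_true(all(unlist(sw[1, vfq25$items$code]) == 0))
  stopped <- best
  stopped$VF5 <- 6L
  expect_true(is.na(vfq_scores(stopped, vfq25)$VF5))
})
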