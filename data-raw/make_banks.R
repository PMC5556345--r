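# Builds the built-in instrument bank JSON files under inst/extdata/banks.
# Run from the package root: Rscript data-raw/make_banks.R
# Bank content: VFQ-25 item codes / summary statements, the 11 sub-domain
# membership of the published scoring conventions, and the VFQ-28-R revision
# rules (exclusions, Appendix additions, collapse maps, 'not sure' -> missing).

suppressMessages(library(jsonlite))

lab_difficulty6 <- c("No difficulty at all", "A little difficulty",
                     "Moderate difficulty", "Extreme difficulty",
                     "Stopped doing this because of eyesight",
                     "Stopped doing this for other reasons")
lab_difficulty5 <- c("No difficulty at all", "A little difficulty",
                     "Moderate difficulty", "Extreme difficulty",
                     "Stopped doing this because of eyesight")
lab_quality <- c("Excellent", "Good", "Fair", "Poor", "Very poor",
                 "Completely blind")
lab_time_best_first <- c("None of the time", "A little of the time",
                         "Some of the time", "Most of the time",
                         "All of the time")
lab_time_worst_first <- rev(lab_time_best_first)
lab_pain <- c("None", "Mild", "Moderate", "Severe", "Very severe")
lab_truefalse <- c("Definitely true", "Mostly true", "Not sure",
                   "Mostly false", "Definitely false")

item <- function(code, statement, labels, reverse = FALSE, stopped = NA) {
  list(code = code, statement = statement,
       n_categories = length(labels), category_labels = labels,
       reverse_scored = reverse,
       stopped_other_reasons_category = if (is.na(stopped)) NULL else stopped)
}

diff6 <- function(code, statement) item(code, statement, lab_difficulty6, stopped = 6L)

items25 <- list(
  item("VF2", "Eyesight quality", lab_quality),
  item("VF3", "Time spent worrying about eyesight", lab_time_best_first),
  item("VF4", "Amount of pain in/around eyes", lab_pain),
  diff6("VF5", "Difficulty reading newspaper print size"),
  diff6("VF6", "Difficulty seeing well up close"),
  diff6("VF7", "Difficulty finding objects"),
  diff6("VF8", "Difficulty reading street signs"),
  diff6("VF9", "Difficulty going downstairs or curbs in dim light"),
  diff6("VF10", "Difficulty with peripheral vision"),
  diff6("VF11", "Difficulty seeing other people reactions"),
  diff6("VF12", "Difficulty matching clothes"),
  diff6("VF13", "Difficulty visiting others"),
  diff6("VF14", "Difficulty going out"),
  item("VF15C", "Difficulty driving during day", lab_difficulty5),
  item("VF16", "Difficulty driving at night", lab_difficulty5),
  item("VF16A", "Difficulty driving in difficult conditions", lab_difficulty5),
  item("VF17", "Limited in time to accomplish activities", lab_time_worst_first, reverse = TRUE),
  item("VF18", "Limited in time at work due to eyesight", lab_time_worst_first, reverse = TRUE),
  item("VF19", "Limited in time due to pain or discomfort around eyes", lab_time_worst_first, reverse = TRUE),
  item("VF20", "Time staying at home due to eyesight", lab_truefalse, reverse = TRUE),
  item("VF21", "Time frustrated due to eyesight", lab_truefalse, reverse = TRUE),
  item("VF22", "Amount of control lost due to eyesight", lab_truefalse, reverse = TRUE),
  item("VF23", "Reliance on what other people say due to eyesight", lab_truefalse, reverse = TRUE),
  item("VF24", "Amount of help from others due to eyesight", lab_truefalse, reverse = TRUE),
  item("VF25", "Embarrassed doing things because of eyesight", lab_truefalse, reverse = TRUE)
)

items_appendix <- list(
  diff6("VFA3", "Difficulty reading small print (e.g. medicine bottle)"),
  diff6("VFA4", "Difficulty reading mail/bills accurately"),
  diff6("VFA5", "Difficulty shaving or putting on makeup"),
  diff6("VFA6", "Difficulty recognizing faces due to eyesight"),
  diff6("VFA7", "Difficulty taking part in outdoor activities"),
  diff6("VFA8", "Difficulty seeing television")
)

subscale <- function(name, codes) list(name = name, item_codes = codes)

subscales25 <- list(
  subscale("general_vision", "VF2"),
  subscale("ocular_pain", c("VF4", "VF19")),
  subscale("near_activities", c("VF5", "VF6", "VF7")),
  subscale("distance_activities", c("VF8", "VF9", "VF14")),
  subscale("social_functioning", c("VF11", "VF13")),
  subscale("mental_health", c("VF3", "VF21", "VF22", "VF25")),
  subscale("role_difficulties", c("VF17", "VF18")),
  subscale("dependency", c("VF20", "VF23", "VF24")),
  subscale("driving", c("VF15C", "VF16", "VF16A")),
  subscale("color_vision", "VF12"),
  subscale("peripheral_vision", "VF10")
)

# Administration set: VFQ-25 plus Appendix items VFA3-VFA8 attached to the
# near / distance activity sub-domains.
subscales25a <- subscales25
subscales25a[[3]]$item_codes <- c(subscales25[[3]]$item_codes, "VFA3", "VFA4", "VFA5")
subscales25a[[4]]$item_codes <- c(subscales25[[4]]$item_codes, "VFA6", "VFA7", "VFA8")

rule <- function(code, action, collapse_map = NULL, missing_categories = NULL) {
  r <- list(item_code = code, action = action)
  if (!is.null(collapse_map)) r$collapse_map <- as.list(setNames(as.integer(collapse_map), seq_along(collapse_map)))
  if (!is.null(missing_categories)) r$missing_categories <- as.integer(missing_categories)
  r
}

# Collapse maps are provisional defaults (not printed in the source
# instrument revision): difficulty items merge valid levels 4 and 5;
# reversed 5-level items merge levels 2 and 3.
collapse_45 <- c(1, 2, 3, 4, 4)
collapse_23 <- c(1, 2, 2, 3, 4)

six_cat_retained <- c("VF5", "VF6", "VF7", "VF8", "VF9", "VF10", "VF11",
                      "VF12", "VF13", "VF14",
                      "VFA3", "VFA4", "VFA5", "VFA6", "VFA7", "VFA8")

rules28 <- c(
  lapply(c("VF2", "VF3", "VF4"), rule, action = "exclude"),
  lapply(six_cat_retained, rule, action = "recode_missing", missing_categories = 6L),
  lapply(c("VF12", "VF13", "VF14"), rule, action = "collapse_levels", collapse_map = collapse_45),
  lapply(c("VF15C", "VF16", "VF16A"), rule, action = "collapse_levels", collapse_map = collapse_45),
  lapply(c("VF18", "VF19", "VF25"), rule, action = "collapse_levels", collapse_map = collapse_23),
  lapply(c("VF20", "VF21", "VF22", "VF23", "VF24"), rule,
         action = "recode_missing", missing_categories = 3L)
)

activity_limitation <- c("VF5", "VF6", "VF7", "VF8", "VF9", "VF10", "VF12",
                         "VF15C", "VF16", "VF16A", "VF17", "VF18", "VF19",
                         "VFA3", "VFA4", "VFA5", "VFA6", "VFA7", "VFA8")
socio_emotional <- c("VF11", "VF13", "VF14", "VF20", "VF21", "VF22",
                     "VF23", "VF24", "VF25")

# Derive the post-revision item definitions by applying the rules to the
# administration-set definitions.
apply_rules_to_item <- function(it, rules) {
  labels <- it$category_labels
  reverse <- it$reverse_scored
  for (r in rules) {
    if (r$item_code != it$code) next
    if (r$action == "exclude") return(NULL)
    if (r$action == "recode_missing") {
      keep <- setdiff(seq_along(labels), r$missing_categories)
      labels <- labels[keep]
    } else if (r$action == "collapse_levels") {
      map <- unlist(r$collapse_map)
      stopifnot(length(map) == length(labels))
      labels <- vapply(seq_len(max(map)), function(new) {
        paste(unique(labels[map == new]), collapse = " / ")
      }, character(1))
    }
  }
  list(code = it$code, statement = it$statement,
       n_categories = length(labels), category_labels = labels,
       reverse_scored = reverse, stopped_other_reasons_category = NULL)
}

items_admin <- c(items25, items_appendix)
# The stopped-for-other-reasons level is handled by a recode_missing rule in
# the revision, so revised items carry no such category.
items28 <- Filter(Negate(is.null), lapply(items_admin, apply_rules_to_item, rules = rules28))
items28 <- items28[order(match(vapply(items28, `[[`, "", "code"),
                               c(activity_limitation, socio_emotional)))]
stopifnot(length(items28) == 28)

banks <- list(
  vfq25 = list(bank_format = 1L, name = "vfq25", items = items25,
               subscales = subscales25, rescore_rules = list()),
  vfq25a = list(bank_format = 1L, name = "vfq25a",
                items = items_admin, subscales = subscales25a,
                rescore_rules = list()),
  vfq28r = list(bank_format = 1L, name = "vfq28r", items = items28,
                subscales = list(
                  subscale("activity_limitation", activity_limitation),
                  subscale("socio_emotional_functioning", socio_emotional)),
                rescore_rules = rules28,
                source_bank = "vfq25a")
)

for (nm in names(banks)) {
  path <- file.path("inst/extdata/banks", paste0(nm, ".json"))
  write_json(banks[[nm]], path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  cat("wrote", path, "\n")
}
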