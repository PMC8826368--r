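#' Autism-Spectrum Quotient item key
#'
#' Item-to-subscale assignment and scoring direction for the 50-item AQ.
#' `agree_keyed = 1` marks items where agreement is the ASD-characteristic
#' response. Subscale codes: `AQ_S` Social Skills, `AQ_C` Communication,
#' `AQ_A` Attention to Detail, `AQ_D` Attention Switching, `AQ_I`
#' Imagination. The key ships as configuration data (the instrument text is
#' not reproduced) and can be swapped for a different translation's keying.
#'
#' @param path optional path to an alternative key CSV with columns `item`,
#'   `subscale`, `agree_keyed`.
#' @return A data frame with 50 rows.
#' @export
aq_item_key <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aq_item_key.csv", package = "visnirs")
  key <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(key) == 50,
            all(c("item", "subscale", "agree_keyed") %in% names(key)))
  key[order(key$item), , drop = FALSE]
}

aq_subscales <- c("AQ_S", "AQ_C", "AQ_A", "AQ_D", "AQ_I")

#' Score a 50-item AQ response set
#'
#' Responses are the 4-point Likert values common to both instrument
#' versions, coded 0 = definitely agree, 1 = slightly agree, 2 = slightly
#' disagree, 3 = definitely disagree.
#'
#' Adult scoring is binary: an item contributes 1 point when the response is
#' in the ASD-characteristic direction (slightly or strongly), 0 otherwise;
#' totals range 0-50 (0-10 per subscale). Child scoring keeps the full
#' Likert range: items are reverse-scored as needed so that 3 is the maximal
#' autistic endorsement; totals range 0-150 (0-30 per subscale).
#'
#' @param responses integer vector of 50 responses in `0:3`.
#' @param version `"adult"` or `"child"`.
#' @param key item key as returned by [aq_item_key()].
#' @return An object of class `aq_record`: list with `version`, `total` and
#'   `subscales` (named integer vector over `AQ_S`, `AQ_C`, `AQ_A`, `AQ_D`,
#'   `AQ_I`); `total` always equals the subscale sum.
#' @examples
#' # every response maximally ASD-characteristic
#' key <- aq_item_key()
#' resp <- ifelse(key$agree_keyed == 1, 0, 3)
#' score_aq(resp, "adult")$total  # 50
#' score_aq(resp, "child")$total  # 150
#' @export
score_aq <- function(responses, version = c("adult", "child"),
                     key = aq_item_key()) {
  version <- match.arg(version)
  if (length(responses) != 50)
    stop("exactly 50 item responses are required", call. = FALSE)
  if (any(is.na(responses)) || !all(responses %in% 0:3))
    stop("responses must be integers in 0:3", call. = FALSE)
  agree <- key$agree_keyed == 1
  item_score <- if (version == "adult") {
    as.integer(ifelse(agree, responses <= 1, responses >= 2))
  } else {
    as.integer(ifelse(agree, 3 - responses, responses))
  }
  subs <- vapply(aq_subscales, function(s)
    sum(item_score[key$subscale == s]), integer(1))
  structure(list(version = version, total = sum(subs), subscales = subs),
            class = "aq_record")
}

#' Clinical risk flag from an AQ total
#'
#' `TRUE` when the total exceeds the clinical threshold: strictly above 32
#' for the adult version, strictly above 76 for the child version. The
#' comparison is strict because a score of exactly 32 occurs in the adult
#' cohort while no participant was flagged at risk.
#'
#' @param aq an `aq_record` from [score_aq()], or a list with `version` and
#'   `total` fields.
#' @return Logical scalar.
#' @export
risk_flag <- function(aq) {
  stopifnot(!is.null(aq$version), !is.null(aq$total))
  thr <- if (aq$version == "adult") 32 else 76
  aq$total > thr
}

#' Packaged demographic/AQ tables
#'
#' The adult (n = 40) and child (n = 19) cohort tables: age, gender, head
#' circumference, cap size, total AQ and the five subscale scores. One child
#' has no AQ questionnaire; those entries are `NA` and are excluded listwise
#' from statistics.
#'
#' @param cohort `"adult"` or `"child"`.
#' @return A tibble with one row per participant.
#' @export
demographics_table <- function(cohort = c("adult", "child")) {
  cohort <- match.arg(cohort)
  path <- system.file("extdata", paste0(cohort, "_demographics.csv"),
                      package = "visnirs")
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  tab$version <- cohort
  tab
}

#' Read / write AQ score tables
#'
#' CSV with columns `subject_id`, `version`, `AQ`, `AQ_S`, `AQ_C`, `AQ_A`,
#' `AQ_D`, `AQ_I`. Missing questionnaires are empty/NA fields.
#'
#' @param path CSV path.
#' @param tab a data frame in the same layout.
#' @return `read_aq_table` returns a tibble; `write_aq_table` returns `path`
#'   invisibly.
#' @export
read_aq_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "version", "AQ", aq_subscales)
  if (!all(need %in% names(tab)))
    stop("AQ table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ok <- !is.na(tab$AQ)
  if (any(tab$AQ[ok] != rowSums(tab[ok, aq_subscales, drop = FALSE])))
    stop("AQ totals must equal the subscale sums", call. = FALSE)
  tibble::as_tibble(tab)
}

#' @rdname read_aq_table
#' @export
write_aq_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
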