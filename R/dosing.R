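#' Clinical plateau specification
#'
#' The four dose plateaus of recreational dextromethorphan use. The
#' published ranges (100-250, 250-400, 450-800, >800 mg) overlap at 250 mg
#' and leave a gap between 400 and 450 mg; the implemented bins are
#' half-open and contiguous, with the gap absorbed into plateau 2:
#' `[100, 250)`, `[250, 450)`, `[450, 800)`, `[800, Inf)`. Doses below
#' 100 mg are in the therapeutic range and map to no plateau.
#'
#' @param lower Numeric vector of lower bounds (mg), one per plateau.
#' @param upper Numeric vector of upper bounds (mg); the last may be `Inf`.
#' @return A tibble with columns `plateau`, `lower_mg`, `upper_mg`.
#' @export
plateau_spec <- function(lower = c(100, 250, 450, 800),
                         upper = c(250, 450, 800, Inf)) {
  stopifnot(
    length(lower) == length(upper), all(lower < upper),
    !is.unsorted(lower), all(utils::head(upper, -1) <= lower[-1])
  )
  tibble::tibble(
    plateau = seq_along(lower),
    lower_mg = lower, upper_mg = upper
  )
}

dose_pattern <- "(?<![0-9a-zA-Z.])([0-9]+(?:\\.[0-9]+)?)[ \t]*(mg|milligrams?|g|grams?)(?![a-zA-Z])"

#' Extract dose mentions from raw text
#'
#' Finds number+unit patterns — `375mg`, `375 mg`, `1.5g`, `600 milligrams`
#' — and converts everything to milligrams (grams x1000). Fluid-ounce and
#' bottle counts are not converted because the concentration depends on the
#' product. Matches are returned in text order.
#'
#' @param text Character vector of raw comment texts.
#' @param id Optional comment ids, recycled against `text`; defaults to the
#'   element index as character.
#' @return A tibble with columns `comment_id`, `value_mg`, `raw_span`; zero
#'   rows when nothing matches.
#' @export
extract_doses <- function(text, id = as.character(seq_along(text))) {
  stopifnot(length(id) == length(text))
  hits <- stringr::str_match_all(
    text,
    stringr::regex(dose_pattern, ignore_case = TRUE)
  )
  rows <- purrr::map2(hits, id, function(m, cid) {
    if (nrow(m) == 0) {
      return(NULL)
    }
    value <- as.numeric(m[, 2])
    unit <- tolower(m[, 3])
    grams <- startsWith(unit, "g")
    tibble::tibble(
      comment_id = cid,
      value_mg = ifelse(grams, value * 1000, value),
      raw_span = m[, 1]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      comment_id = character(), value_mg = numeric(),
      raw_span = character()
    ))
  }
  out[out$value_mg > 0, ]
}

#' Assign a dose to its plateau
#'
#' Returns the plateau whose half-open interval `[lower, upper)` contains
#' the dose, `NA` for doses below the first plateau (therapeutic range,
#' excluded) and for doses above `max_plausible_mg`, which are treated as
#' hyperbole.
#'
#' @param value_mg Numeric vector of doses in mg.
#' @param spec Plateau specification from [plateau_spec()].
#' @param max_plausible_mg Doses above this are excluded (default 5000 mg).
#' @return Integer vector of plateau ids, `NA` where excluded.
#' @export
assign_plateau <- function(value_mg, spec = plateau_spec(),
                           max_plausible_mg = 5000) {
  out <- rep(NA_integer_, length(value_mg))
  for (i in seq_len(nrow(spec))) {
    hit <- value_mg >= spec$lower_mg[i] & value_mg < spec$upper_mg[i]
    out[hit] <- spec$plateau[i]
  }
  out[value_mg > max_plausible_mg] <- NA_integer_
  out
}

#' Histogram of dose mentions
#'
#' Counts mentions per half-open dose bin `[k*b, (k+1)*b)` mg; the
#' conventional bin width for this distribution is 200 mg.
#'
#' @param doses Tibble from [extract_doses()].
#' @param bin_mg Bin width in mg (>= 1).
#' @return A tibble with columns `bin_lo`, `bin_hi`, `n`.
#' @export
dose_histogram <- function(doses, bin_mg = 200) {
  stopifnot(bin_mg >= 1)
  bin_histogram(doses$value_mg, bin_mg)
}

#' Pool comment tokens by plateau
#'
#' Each comment mentioning at least one in-range dose contributes its
#' tokens to exactly one plateau pool; comments with no in-range dose are
#' excluded. When a comment mentions several in-range doses the assignment
#' rule is configurable: `"first"` (default) uses the first in-range
#' mention in text order, `"max"` the largest, `"drop"` discards the
#' comment as ambiguous. Digits are stripped from pooled tokens (the dose
#' numerals themselves must not become plateau vocabulary).
#'
#' @param tokenized Tibble from [tokenize_corpus()] (digits still present).
#' @param doses Tibble from [extract_doses()].
#' @param spec Plateau specification.
#' @param rule Multi-mention rule: "first", "max" or "drop".
#' @param max_plausible_mg Passed to [assign_plateau()].
#' @return A list with elements `pools` (tibble `plateau`, `term`, `count`),
#'   `assignments` (tibble `id`, `plateau`, `dose_mg`), `n_excluded`.
#' @export
build_plateau_corpora <- function(tokenized, doses, spec = plateau_spec(),
                                  rule = c("first", "max", "drop"),
                                  max_plausible_mg = 5000) {
  rule <- match.arg(rule)
  doses$plateau <- assign_plateau(doses$value_mg, spec, max_plausible_mg)
  in_range <- doses[!is.na(doses$plateau), ]
  pick <- function(df) {
    if (rule == "drop" && nrow(df) > 1 && length(unique(df$plateau)) > 1) {
      return(df[0, ])
    }
    if (rule == "max") {
      return(df[which.max(df$value_mg), ])
    }
    df[1, ] # first mention in text order
  }
  assigned <- in_range |>
    dplyr::group_by(.data$comment_id) |>
    dplyr::group_modify(~ pick(.x)) |>
    dplyr::ungroup()
  assignments <- tibble::tibble(
    id = assigned$comment_id,
    plateau = assigned$plateau,
    dose_mg = assigned$value_mg
  )
  merged <- dplyr::inner_join(tokenized, assignments, by = "id")
  pool_rows <- purrr::map(seq_len(nrow(merged)), function(i) {
    tok <- gsub("[0-9]", "", merged$tokens[[i]])
    tok <- tok[nzchar(tok)]
    if (length(tok) == 0) {
      return(NULL)
    }
    tibble::tibble(plateau = merged$plateau[i], term = tok)
  })
  pools <- dplyr::bind_rows(pool_rows)
  if (nrow(pools) == 0) {
    pools <- tibble::tibble(
      plateau = integer(), term = character(),
      count = integer()
    )
  } else {
    pools <- pools |>
      dplyr::count(.data$plateau, .data$term, name = "count")
  }
  list(
    pools = pools,
    assignments = assignments,
    n_excluded = nrow(tokenized) - nrow(merged)
  )
}
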