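#' Guideline rule sets: the manual consensus as executable rules
#'
#' The manually refined consensus gold standard is realised here as an
#' ordered list of declarative transformations over an annotation set, one
#' per refined-guideline change:
#'
#' 1. `no_subtoken` — spans are snapped outward to whole tokens
#'    (an instance like *34-årig* must be annotated in its entirety);
#' 2. `location_merge` — `Street_Address`, `Town`, `Municipality`,
#'    `Country` and `Organization` are relabelled to the more general
#'    `Location`;
#' 3. `merge_adjacent` — adjacent same-label annotations separated only by
#'    punctuation/whitespace are merged, giving addresses and unit names
#'    their largest possible span;
#' 4. `date_no_weekday` — leading/trailing weekday words are stripped from
#'    `Date_Part`/`Full_Date` spans (deleting the annotation when nothing
#'    remains); the `Date_Part` / `Full_Date` division itself is kept;
#' 5. `unit_specificity` — a `Health_Care_Unit` whose surface is a generic
#'    unit term ("Geriatriken") with no specific name is deleted;
#' 6. `delete_classes` — the `Relation` and `Ethnicity` classes are deleted
#'    (judged not to risk identifying patients).
#'
#' Boundary fixes run before label logic and deletions run last, so the
#' change log is complete.  The engine accepts either the raw annotator
#' sets or an automatic consensus as input.
#'
#' @param rules character vector of rule names, in application order.
#' @param weekday_lexicon,generic_unit_lexicon term lists (case-insensitive
#'   match) for the date and unit rules; defaults are shipped as plain-text
#'   data.
#' @param delete_labels classes removed by `delete_classes`.
#' @return `guideline_ruleset()` returns a `guideline_ruleset` list.
#' @export
guideline_ruleset <- function(rules = c("no_subtoken", "location_merge",
                                        "merge_adjacent", "date_no_weekday",
                                        "unit_specificity", "delete_classes"),
                              weekday_lexicon = read_lexicon("weekdays"),
                              generic_unit_lexicon = read_lexicon("generic_units"),
                              delete_labels = c("Relation", "Ethnicity")) {
  known <- c("no_subtoken", "location_merge", "merge_adjacent",
             "date_no_weekday", "unit_specificity", "delete_classes")
  if (anyDuplicated(rules)) stop("rule names must be unique")
  bad <- setdiff(rules, known)
  if (length(bad)) stop("unknown rule(s): ", paste(bad, collapse = ", "))
  structure(list(rules = rules, weekday_lexicon = weekday_lexicon,
                 generic_unit_lexicon = generic_unit_lexicon,
                 delete_labels = delete_labels),
            class = "guideline_ruleset")
}

#' @param path YAML file with fields `rules`, `weekday_lexicon`,
#'   `generic_unit_lexicon`, `delete_labels` (missing fields take the
#'   defaults).
#' @describeIn guideline_ruleset Read a rule set from a YAML config.
#' @export
read_guideline_ruleset <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  for (f in c("rules", "weekday_lexicon", "generic_unit_lexicon",
              "delete_labels"))
    if (!is.null(cfg[[f]])) args[[f]] <- unlist(cfg[[f]])
  do.call(guideline_ruleset, args)
}

.location_sources <- c("Street_Address", "Town", "Municipality", "Country",
                       "Organization")

#' Apply guideline rules to an annotation set
#'
#' Rules are applied in order; each annotation is visited once per rule.
#' Every deletion, relabelling and boundary move is recorded in the change
#' log, so `nrow(output) == nrow(input) - deletions` always holds
#' (relabels and boundary moves conserve the count, except where a boundary
#' fix merges two annotations into one, which the log records as a merge
#' deletion).
#'
#' @param set an [annotation_set()] (non-overlapping).
#' @param corpus the [phi_corpus()] giving text and token geometry.
#' @param rules a [guideline_ruleset()].
#' @return The transformed [annotation_set()] with attribute `changelog`: a
#'   data frame with columns `rule`, `action` (`delete`, `relabel`, `move`,
#'   `merge`), `doc_id`, `start`, `end`, `label`, `detail`.
#' @export
apply_guidelines <- function(set, corpus, rules = guideline_ruleset()) {
  stopifnot(inherits(rules, "guideline_ruleset"))
  df <- as.data.frame(set)
  log <- list()
  note <- function(rule, action, row, detail = "") {
    log[[length(log) + 1L]] <<- data.frame(
      rule = rule, action = action, doc_id = row$doc_id,
      start = row$start, end = row$end, label = row$label,
      detail = detail, stringsAsFactors = FALSE)
  }
  for (rule in rules$rules) {
    if (!nrow(df)) break
    if (rule == "no_subtoken") {
      for (i in seq_len(nrow(df))) {
        sp <- snap_span(df$start[i], df$end[i], corpus[[df$doc_id[i]]]$tokens)
        if (is.null(sp)) next
        if (sp[1] != df$start[i] || sp[2] != df$end[i]) {
          note(rule, "move", df[i, ],
               sprintf("%d-%d -> %d-%d", df$start[i], df$end[i], sp[1], sp[2]))
          df$start[i] <- sp[1]; df$end[i] <- sp[2]
        }
      }
      # snapping can make neighbours collide; same-label pairs merge (logged
      # as a merge deletion), different labels are trimmed
      df <- resolve_snap_overlaps(df, rule, note)
    } else if (rule == "location_merge") {
      hit <- df$label %in% .location_sources
      for (i in which(hit)) note(rule, "relabel", df[i, ],
                                 paste(df$label[i], "-> Location"))
      df$label[hit] <- "Location"
    } else if (rule == "merge_adjacent") {
      df <- merge_adjacent_same_label(df, corpus, rule, note)
    } else if (rule == "date_no_weekday") {
      drop <- logical(nrow(df))
      for (i in which(df$label %in% c("Date_Part", "Full_Date"))) {
        doc <- corpus[[df$doc_id[i]]]
        sp <- strip_weekdays(df$start[i], df$end[i], doc,
                             rules$weekday_lexicon)
        if (is.null(sp)) {
          note(rule, "delete", df[i, ], "weekday-only date")
          drop[i] <- TRUE
        } else if (sp[1] != df$start[i] || sp[2] != df$end[i]) {
          note(rule, "move", df[i, ],
               sprintf("%d-%d -> %d-%d", df$start[i], df$end[i], sp[1], sp[2]))
          df$start[i] <- sp[1]; df$end[i] <- sp[2]
        }
      }
      df <- df[!drop, , drop = FALSE]
    } else if (rule == "unit_specificity") {
      drop <- logical(nrow(df))
      gen <- tolower(trimws(rules$generic_unit_lexicon))
      for (i in which(df$label == "Health_Care_Unit")) {
        doc <- corpus[[df$doc_id[i]]]
        surf <- substring(doc$text, df$start[i] + 1L, df$end[i])
        words <- tolower(strsplit(trimws(surf), "\\s+")[[1]])
        if (all(words %in% gen)) {
          note(rule, "delete", df[i, ], paste("generic unit:", surf))
          drop[i] <- TRUE
        }
      }
      df <- df[!drop, , drop = FALSE]
    } else if (rule == "delete_classes") {
      drop <- df$label %in% rules$delete_labels
      for (i in which(drop)) note(rule, "delete", df[i, ], "class deleted")
      df <- df[!drop, , drop = FALSE]
    }
  }
  out <- annotation_set(df, validate = FALSE)
  changelog <- do.call(rbind, c(log, list(NULL)))
  if (is.null(changelog))
    changelog <- data.frame(rule = character(), action = character(),
                            doc_id = character(), start = integer(),
                            end = integer(), label = character(),
                            detail = character(), stringsAsFactors = FALSE)
  attr(out, "changelog") <- changelog
  out
}

# merge same-label overlaps after snapping; trim later different-label ones
resolve_snap_overlaps <- function(df, rule, note) {
  df <- df[order(df$doc_id, df$start, df$end), , drop = FALSE]
  i <- 2L
  while (i <= nrow(df)) {
    if (df$doc_id[i] == df$doc_id[i - 1L] &&
        df$start[i] < df$end[i - 1L]) {
      if (df$label[i] == df$label[i - 1L]) {
        note(rule, "merge", df[i, ], "merged into preceding span")
        df$end[i - 1L] <- max(df$end[i - 1L], df$end[i])
        df <- df[-i, , drop = FALSE]
        next
      }
      note(rule, "move", df[i, ], "trimmed to follow preceding span")
      df$start[i] <- df$end[i - 1L]
      if (df$start[i] >= df$end[i]) {
        note(rule, "delete", df[i, ], "emptied by trim")
        df <- df[-i, , drop = FALSE]
        next
      }
    }
    i <- i + 1L
  }
  df
}

# merge adjacent same-label annotations separated only by punct/whitespace
merge_adjacent_same_label <- function(df, corpus, rule, note) {
  df <- df[order(df$doc_id, df$start, df$end), , drop = FALSE]
  i <- 2L
  while (i <= nrow(df)) {
    if (df$doc_id[i] == df$doc_id[i - 1L] &&
        df$label[i] == df$label[i - 1L]) {
      gap <- substring(corpus[[df$doc_id[i]]]$text,
                       df$end[i - 1L] + 1L, df$start[i])
      if (!grepl("[\\p{L}\\p{N}]", gap, perl = TRUE) &&
          !grepl("\n", gap, fixed = TRUE)) {
        note(rule, "merge", df[i, ], "adjacent same-label merge")
        df$end[i - 1L] <- df$end[i]
        df <- df[-i, , drop = FALSE]
        next
      }
    }
    i <- i + 1L
  }
  df
}

# strip leading/trailing weekday tokens from a date span; NULL if nothing
# non-weekday remains
strip_weekdays <- function(start, end, doc, weekdays) {
  toks <- doc$tokens
  hit <- which(toks[, 1] < end & toks[, 2] > start)
  if (!length(hit)) return(NULL)
  words <- tolower(substring(doc$text, toks[hit, 1] + 1L, toks[hit, 2]))
  wd <- tolower(weekdays)
  lo <- 1L; hi <- length(hit)
  while (lo <= hi && words[lo] %in% wd) lo <- lo + 1L
  while (hi >= lo && words[hi] %in% wd) hi <- hi - 1L
  if (lo > hi) return(NULL)
  c(max(start, toks[hit[lo], 1L]), min(end, toks[hit[hi], 2L]))
}
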