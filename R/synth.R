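#' Synthetic clinical-style corpora with gold PHI annotations
#'
#' The generator assembles pseudo-clinical Swedish-flavoured sentences from
#' templates, inserting PHI surface forms drawn from entirely fictional
#' lexicons at recorded character offsets, so every downstream stage of the
#' pipeline (agreement, consensus, guideline rules, CRF training and
#' evaluation) runs without any real patient data.  Class frequencies are
#' skewed by default — `Health_Care_Unit` is by far the most frequent class,
#' as in real clinical de-identification corpora.  Two deliberate wrinkles
#' make the guideline rule engine testable: generic health-care-unit terms
#' ("Geriatriken") appear *without* gold annotation, and some date
#' insertions are preceded by a weekday word that is *outside* the gold
#' span.
#'
#' @param n_documents number of documents to generate.
#' @param tokens_per_doc target mean tokens per document.
#' @param phi_per_doc gold PHI insertions per document.
#' @param class_frequencies named non-negative weights over PHI labels; at
#'   least one must be positive.  Normalised internally.
#' @param lexicons named list mapping each positive-weight label to a
#'   non-empty character vector of surface forms.
#' @param weekday_rate probability that a date insertion is preceded by a
#'   weekday word (outside the gold span).
#' @param distractor_rate expected generic-unit distractor sentences per
#'   document (unannotated).
#' @param seed integer seed; identical configs give byte-identical corpora.
#' @return `synth_config()` returns a `synth_config` list.
#' @examples
#' cfg <- synth_config(n_documents = 2, seed = 7)
#' gc <- generate_gold_corpus(cfg)
#' gc$gold
#' @export
synth_config <- function(n_documents = 100L,
                         tokens_per_doc = 200L,
                         phi_per_doc = 10L,
                         class_frequencies = default_class_frequencies(),
                         lexicons = default_lexicons(),
                         weekday_rate = 0.3,
                         distractor_rate = 0.6,
                         seed = 1L) {
  w <- class_frequencies
  stopifnot(is.numeric(w), !is.null(names(w)), all(w >= 0))
  if (!any(w > 0)) stop("class_frequencies must have at least one positive weight")
  for (l in names(w)[w > 0])
    if (is.null(lexicons[[l]]) || !length(lexicons[[l]]))
      stop("no lexicon for positive-weight label ", l)
  structure(list(n_documents = as.integer(n_documents),
                 tokens_per_doc = as.integer(tokens_per_doc),
                 phi_per_doc = as.integer(phi_per_doc),
                 class_frequencies = w / sum(w),
                 lexicons = lexicons,
                 weekday_rate = weekday_rate,
                 distractor_rate = distractor_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

read_lexicon <- function(name) {
  path <- system.file("extdata", "lexicons", paste0(name, ".txt"),
                      package = "phigold")
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @describeIn synth_config Default class weights (percent-scale, normalised
#'   on use); `Health_Care_Unit` strictly dominant.
#' @export
default_class_frequencies <- function() {
  c(Health_Care_Unit = 30, First_Name = 8, Last_Name = 8,
    Clinician_First_Name = 4, Clinician_Last_Name = 4,
    Full_Date = 8, Date_Part = 8, Age = 6, Age_Over_89 = 1,
    Phone_Number = 6, Town = 5, Street_Address = 3, Municipality = 1,
    Country = 2, Organization = 2, Relation = 2, Ethnicity = 2)
}

#' @describeIn synth_config Default fictional Swedish-flavoured lexicons
#'   (shipped as plain-text files, plus programmatic age/date/phone
#'   patterns).
#' @export
default_lexicons <- function() {
  fn <- read_lexicon("first_names"); ln <- read_lexicon("last_names")
  ages <- c(paste0(25:89, "-årig"), paste0(30:70, " år"))
  ages89 <- c(paste0(90:99, "-årig"), paste0(91:99, " år"))
  dates_full <- c(sprintf("20%02d-%02d-%02d", rep(c(7, 8, 9), each = 12),
                          rep(1:12, 3), (seq_len(36) %% 27) + 1),
                  sprintf("%d/%d 200%d", (seq_len(12) %% 27) + 1, 1:12,
                          rep(7:9, 4)))
  dates_part <- c(sprintf("%d/%d", (seq_len(24) %% 27) + 1,
                          (seq_len(24) %% 12) + 1),
                  paste0(c(3, 7, 12, 19, 24, 28), " mars"),
                  paste0(c(2, 9, 15, 21), " oktober"))
  phones <- c(sprintf("08-517 7%02d %02d", seq_len(20) * 3 %% 100,
                      seq_len(20) * 7 %% 100),
              sprintf("070-%03d %02d %02d", seq_len(10) * 37 %% 1000,
                      seq_len(10) * 11 %% 100, seq_len(10) * 13 %% 100))
  list(First_Name = fn, Last_Name = ln,
       Clinician_First_Name = fn, Clinician_Last_Name = ln,
       Patient_First_Name = fn, Patient_Last_Name = ln,
       Relative_First_Name = fn, Relative_Last_Name = ln,
       Age = ages, Age_Over_89 = ages89,
       Full_Date = dates_full, Date_Part = dates_part,
       Phone_Number = phones,
       Town = read_lexicon("towns"),
       Street_Address = read_lexicon("streets"),
       Municipality = read_lexicon("municipalities"),
       Country = read_lexicon("countries"),
       Organization = read_lexicon("organizations"),
       Health_Care_Unit = read_lexicon("units"),
       Relation = read_lexicon("relations"),
       Ethnicity = read_lexicon("ethnicities"))
}

# sentence templates: "%s" marks the PHI slot.  Context words carry class
# signal, as section headers and phrases do in real records.
.phi_templates <- list(
  First_Name = c("Patienten %s inkom via akutintag.",
                 "Samtal med %s angående provsvar."),
  Last_Name = c("Pat %s söker för huvudvärk sedan tre dagar.",
                "Journalanteckning gäller %s enligt remiss."),
  Clinician_First_Name = c("Ansvarig läkare %s ordinerade vila.",
                           "Dr %s bedömde såret vid ronden."),
  Clinician_Last_Name = c("Signerat av överläkare %s vid utskrivning.",
                          "Kontakta ssk. %s vid försämring."),
  Patient_First_Name = c("Patienten %s uppger smärta i vänster knä."),
  Patient_Last_Name = c("Pat %s planeras för återbesök."),
  Relative_First_Name = c("Anhörig %s informerades per telefon."),
  Relative_Last_Name = c("Närstående %s närvarade vid samtalet."),
  Age = c("En %s man söker för andfåddhet.",
          "Pat är en %s kvinna med hypertoni."),
  Age_Over_89 = c("En %s kvinna inkommer med fallskada.",
                  "Pat är en %s man, tidigare frisk."),
  Full_Date = c("Opererad %s utan komplikationer.",
                "Utskriven %s till hemmet."),
  Date_Part = c("Återbesök %s på mottagningen.",
                "Provtagning planerad %s hos ssk."),
  Phone_Number = c("Nås på telefon %s dagtid.",
                   "Anhörig nås via %s vid behov."),
  Town = c("Pat bor i %s med sin familj.",
           "Flyttade nyligen till %s från annan ort."),
  Street_Address = c("Hemadress %s enligt folkbokföring.",
                     "Bor på %s i markplan."),
  Municipality = c("Hemtjänst beviljad av %s sedan våren.",
                   "Biståndsbeslut fattat av %s i år."),
  Country = c("Nyligen hemkommen från resa till %s.",
              "Vårdad tidigare i %s för samma besvär."),
  Organization = c("Intyg skickat till %s per post.",
                   "Kontakt etablerad med %s för uppföljning."),
  Health_Care_Unit = c("Remitterad till %s för vidare utredning.",
                       "Tidigare vårdad på %s i två veckor.",
                       "Överflyttad från %s efter stabilisering.",
                       "Uppföljning sker vid %s nästa månad."),
  Relation = c("Bor tillsammans med %s i lägenhet.",
               "Kom i sällskap med %s till akuten."),
  Ethnicity = c("Pat är %s och önskar tolk vid behov.")
)

.filler_sentences <- c(
  "Lungor auskulteras med rena andningsljud bilateralt.",
  "Blodtryck 130/80 och puls 72 regelbunden.",
  "Pat mår bra och är opåverkad i vila.",
  "Fortsatt ordination enligt tidigare lista.",
  "Såret ser fint ut utan tecken till infektion.",
  "Planerar uppföljande provtagning om två veckor.",
  "EKG visar sinusrytm utan anmärkning.",
  "Pat informerad om egenvård och varningstecken.",
  "Ingen feber under det senaste dygnet.",
  "Status i övrigt väsentligen utan anmärkning.",
  "Smärtlindring med god effekt enligt pat.",
  "Neurologiskt status är invändningsfritt."
)

.distractor_templates <- c(
  "Kontakt tagen med %s för bedömning.",
  "Svar inväntas från %s under veckan."
)

.weekday_date_template <- "Besök bokat %s på mottagningen."

#' Generate a gold-annotated synthetic corpus
#'
#' @param cfg a [synth_config()].
#' @return A list with `corpus` (a [phi_corpus()]) and `gold` (an
#'   [annotation_set()] with source `"gold"`); every gold annotation's text
#'   slice equals the lexicon form inserted.
#' @export
generate_gold_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  labels <- names(cfg$class_frequencies)[cfg$class_frequencies > 0]
  probs <- cfg$class_frequencies[labels]
  weekdays <- read_lexicon("weekdays")
  generics <- read_lexicon("generic_units")
  docs <- vector("list", cfg$n_documents)
  gold_rows <- vector("list", cfg$n_documents)
  # filler sentences average ~7 tokens, PHI sentences ~9 (multi-word
  # surfaces); aim the total token count at tokens_per_doc
  n_filler <- max(1L, round(cfg$tokens_per_doc / 7) -
                    round(1.3 * cfg$phi_per_doc))
  for (i in seq_len(cfg$n_documents)) {
    did <- sprintf("doc%04d", i)
    labs <- sample(labels, cfg$phi_per_doc, replace = TRUE, prob = probs)
    sent <- list()
    for (l in labs) {
      surf <- sample(cfg$lexicons[[l]], 1L)
      if (l %in% c("Full_Date", "Date_Part") &&
          runif(1) < cfg$weekday_rate) {
        wd <- sample(weekdays, 1L)
        tmpl <- .weekday_date_template
        pre <- sub("%s.*$", "", tmpl)
        slot <- paste0(wd, " ", surf)
        txt <- sprintf(tmpl, slot)
        off <- nchar(pre) + nchar(wd) + 1L   # weekday outside gold span
      } else {
        tmpl <- sample(.phi_templates[[l]], 1L)
        pre <- sub("%s.*$", "", tmpl)
        txt <- sprintf(tmpl, surf)
        off <- nchar(pre)
      }
      sent[[length(sent) + 1L]] <-
        list(text = txt,
             ann = data.frame(start = off, end = off + nchar(surf),
                              label = l, stringsAsFactors = FALSE))
    }
    nd <- rbinom(1L, 3L, min(1, cfg$distractor_rate / 3))
    for (k in seq_len(nd)) {
      txt <- sprintf(sample(.distractor_templates, 1L), sample(generics, 1L))
      sent[[length(sent) + 1L]] <- list(text = txt, ann = NULL)
    }
    for (k in seq_len(n_filler)) {
      txt <- sample(.filler_sentences, 1L)
      sent[[length(sent) + 1L]] <- list(text = txt, ann = NULL)
    }
    sent <- sent[sample.int(length(sent))]
    cursor <- 0L
    pieces <- character(length(sent))
    anns <- list()
    for (k in seq_along(sent)) {
      pieces[k] <- sent[[k]]$text
      if (!is.null(sent[[k]]$ann)) {
        a <- sent[[k]]$ann
        a$start <- a$start + cursor
        a$end <- a$end + cursor
        anns[[length(anns) + 1L]] <- a
      }
      cursor <- cursor + nchar(sent[[k]]$text) + 1L   # "\n" separator
    }
    text <- paste(pieces, collapse = "\n")
    docs[[i]] <- phi_document(did, text)
    if (length(anns)) {
      g <- do.call(rbind, anns)
      g$doc_id <- did
      gold_rows[[i]] <- g
    }
  }
  gold <- annotation_set(do.call(rbind, c(gold_rows, list(NULL))),
                         source = "gold")
  list(corpus = phi_corpus(docs), gold = gold)
}

#' Annotator error models and annotator simulation
#'
#' An error model describes one imperfect annotator: each gold annotation is
#' independently dropped with probability `miss_rate`; survivors are
#' relabelled by drawing from the confusion row of their true label and,
#' with probability `boundary_jitter`, have one boundary moved by one token
#' (shrunk or extended, feasibility permitting).  Spurious annotations —
#' `spurious_rate` expected per document — are added on token spans that
#' overlap neither the gold nor each other, so the bookkeeping between gold
#' and simulated sets stays exact.
#'
#' @param miss_rate probability of dropping a gold annotation.
#' @param boundary_jitter probability of a one-token boundary move.
#' @param confusion named list: true label -> named probability vector over
#'   reported labels (each row sums to 1).  Labels absent from the list are
#'   reported faithfully.
#' @param spurious_rate expected spurious annotations per document.
#' @param seed integer seed making the simulation deterministic.
#' @return `annotator_error_model()` returns an `annotator_error_model`.
#' @export
annotator_error_model <- function(miss_rate = 0, boundary_jitter = 0,
                                  confusion = list(), spurious_rate = 0,
                                  seed = 1L) {
  stopifnot(miss_rate >= 0, miss_rate <= 1,
            boundary_jitter >= 0, boundary_jitter <= 1,
            spurious_rate >= 0)
  for (l in names(confusion)) {
    row <- confusion[[l]]
    stopifnot(is.numeric(row), !is.null(names(row)), all(row >= 0))
    if (abs(sum(row) - 1) > 1e-8)
      stop("confusion row for ", l, " does not sum to 1")
  }
  structure(list(miss_rate = miss_rate, boundary_jitter = boundary_jitter,
                 confusion = confusion, spurious_rate = spurious_rate,
                 seed = as.integer(seed)),
            class = "annotator_error_model")
}

# confusion partner: specificity parent when one exists, else a fixed
# plausible confusand, else none (identity row)
.confusion_partner <- c(.catalog_specificity,
                        Health_Care_Unit = "Organization",
                        Full_Date = "Date_Part", Date_Part = "Full_Date",
                        First_Name = "Last_Name", Last_Name = "First_Name")

#' @param labels labels to build rows for.
#' @param diag probability mass kept on the true label.
#' @describeIn annotator_error_model Confusion rows putting `1 - diag` on
#'   each label's most plausible confusand (its generic parent where one
#'   exists).
#' @export
default_confusion <- function(labels = .catalog_labels, diag = 0.96) {
  out <- list()
  for (l in labels) {
    if (l %in% names(.confusion_partner)) {
      p <- unname(.confusion_partner[[l]])
      out[[l]] <- setNames(c(diag, 1 - diag), c(l, p))
    }
  }
  out
}

#' @describeIn annotator_error_model Three default annotators calibrated so
#'   that, on the default corpus, mean pairwise exact-match agreement lands
#'   near 0.65 F-score with clearly unequal per-annotator totals (miss rates
#'   0.05 / 0.10 / 0.25).
#' @param base_seed seed the three annotator seeds are derived from.
#' @export
default_error_models <- function(base_seed = 1L) {
  miss <- c(0.05, 0.10, 0.25)
  lapply(seq_along(miss), function(i)
    annotator_error_model(miss_rate = miss[i], boundary_jitter = 0.08,
                          confusion = default_confusion(),
                          spurious_rate = 0.4,
                          seed = (as.integer(base_seed) + 101L * i) %% .Machine$integer.max))
}

#' @param gold gold [annotation_set()] (non-overlapping).
#' @param model an `annotator_error_model`.
#' @param source_id source identifier for the simulated set.
#' @param corpus the [phi_corpus()] the gold set annotates (needed for token
#'   geometry).
#' @describeIn annotator_error_model Simulate one annotator over a gold set.
#' @export
simulate_annotator <- function(gold, model, source_id, corpus) {
  stopifnot(inherits(model, "annotator_error_model"),
            inherits(corpus, "phi_corpus"))
  set.seed(model$seed)
  df <- as.data.frame(gold)
  keep <- runif(nrow(df)) >= model$miss_rate
  df <- df[keep, , drop = FALSE]
  if (nrow(df)) {
    # relabel via confusion rows
    for (i in seq_len(nrow(df))) {
      row <- model$confusion[[df$label[i]]]
      if (!is.null(row))
        df$label[i] <- sample(names(row), 1L, prob = row)
    }
    # boundary jitter by one token
    jit <- runif(nrow(df)) < model$boundary_jitter
    for (d in unique(df$doc_id)) {
      idx <- which(df$doc_id == d)
      toks <- corpus[[d]]$tokens
      for (i in idx[jit[idx]]) {
        ti <- which(toks[, 1] >= df$start[i] & toks[, 2] <= df$end[i])
        if (!length(ti)) next
        moves <- list()
        if (length(ti) > 1L) {
          moves <- c(moves, list(c(toks[ti[2L], 1L], df$end[i])),
                     list(c(df$start[i], toks[ti[length(ti) - 1L], 2L])))
        }
        if (ti[1L] > 1L) {
          cand <- c(toks[ti[1L] - 1L, 1L], df$end[i])
          if (!any(df$doc_id == d & df$start < cand[2] & df$end > cand[1] &
                   seq_len(nrow(df)) != i))
            moves <- c(moves, list(cand))
        }
        if (ti[length(ti)] < nrow(toks)) {
          cand <- c(df$start[i], toks[ti[length(ti)] + 1L, 2L])
          if (!any(df$doc_id == d & df$start < cand[2] & df$end > cand[1] &
                   seq_len(nrow(df)) != i))
            moves <- c(moves, list(cand))
        }
        if (length(moves)) {
          mv <- moves[[sample.int(length(moves), 1L)]]
          df$start[i] <- mv[1]; df$end[i] <- mv[2]
        }
      }
    }
  }
  # spurious annotations on unoccupied token spans, never overlapping gold
  labs <- unique(as.data.frame(gold)$label)
  if (!length(labs)) labs <- "PHI"
  spur <- list()
  if (model$spurious_rate > 0) {
    for (d in names(corpus)) {
      n_sp <- stats::rpois(1L, model$spurious_rate)
      if (!n_sp) next
      toks <- corpus[[d]]$tokens
      if (!nrow(toks)) next
      occupied <- rep(FALSE, nrow(toks))
      gsub_ <- gold[gold$doc_id == d, , drop = FALSE]
      dsub <- df[df$doc_id == d, , drop = FALSE]
      for (j in seq_len(nrow(gsub_)))
        occupied <- occupied | (toks[, 1] < gsub_$end[j] &
                                  toks[, 2] > gsub_$start[j])
      for (j in seq_len(nrow(dsub)))
        occupied <- occupied | (toks[, 1] < dsub$end[j] &
                                  toks[, 2] > dsub$start[j])
      for (k in seq_len(n_sp)) {
        len <- sample(1:2, 1L)
        free <- which(!occupied)
        free <- free[free + len - 1L <= nrow(toks)]
        free <- free[vapply(free, function(f)
          !any(occupied[f:(f + len - 1L)]), logical(1))]
        if (!length(free)) break
        f <- free[sample.int(length(free), 1L)]
        occupied[f:(f + len - 1L)] <- TRUE
        spur[[length(spur) + 1L]] <- data.frame(
          doc_id = d, start = toks[f, 1L], end = toks[f + len - 1L, 2L],
          label = sample(labs, 1L), source = source_id,
          stringsAsFactors = FALSE)
      }
    }
  }
  df$source <- rep(source_id, nrow(df))
  annotation_set(do.call(rbind, c(list(df), spur, list(NULL))),
                 validate = FALSE)
}

#' Build a full synthetic annotation study
#'
#' Generates a gold corpus from `cfg` and simulates one annotator per error
#' model, bundling everything as an [annotation_study()].
#'
#' @param cfg a [synth_config()].
#' @param models list of at least two [annotator_error_model()]s (the
#'   default mirrors a three-annotator study).
#' @param source_ids annotator identifiers.
#' @return An [annotation_study()] whose `gold` element holds the generating
#'   gold set.
#' @export
build_annotation_study <- function(cfg, models = default_error_models(cfg$seed),
                                   source_ids = paste0("annotator", seq_along(models))) {
  if (length(models) < 2L) stop("an annotation study needs at least 2 annotators")
  gc <- generate_gold_corpus(cfg)
  sets <- lapply(seq_along(models), function(i)
    simulate_annotator(gc$gold, models[[i]], source_ids[i], gc$corpus))
  names(sets) <- source_ids
  annotation_study(gc$corpus, sets, gold = gc$gold)
}
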