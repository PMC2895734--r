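#' Class schemes: label-space mappings for merging experiments
#'
#' A class scheme maps every source label to a target label or to deletion,
#' defining one experiment in a progressive class-coarsening series: from
#' the full 28-class catalog down to a single generic `PHI` class.  The
#' exact memberships of the historical intermediate schemes were never
#' published; the shipped series follows the stated principles (name
#' refinements fold into `First_Name`/`Last_Name`, then into `Name`; the
#' five location classes fold into `Location`; ages into `Age`; the
#' `Date_Part`/`Full_Date` division is kept until the final merges) and is
#' **non-canonical** — schemes are configurable precisely because of that
#' gap.  Anchors that are known: the third and fourth experiments use 16
#' and 13 classes, and the last merges everything into `PHI`.
#'
#' @param name scheme name.
#' @param mapping named character vector: source label -> target label, or
#'   the string `"DELETE"` to drop the class.  Labels absent from the
#'   mapping map to themselves when `default_identity` is `TRUE`.
#' @param source_labels the label set the mapping is total over.
#' @param default_identity complete the mapping with identity rows.
#' @return A `class_scheme` with elements `name`, `mapping` (total over
#'   `source_labels`), and `labels` (the resulting label set).
#' @export
class_scheme <- function(name, mapping, source_labels = .catalog_labels,
                         default_identity = TRUE) {
  full <- setNames(source_labels, source_labels)
  if (length(mapping)) {
    stopifnot(!is.null(names(mapping)))
    unknown <- setdiff(names(mapping), source_labels)
    if (length(unknown))
      stop("mapping refers to labels outside the source catalog: ",
           paste(unknown, collapse = ", "))
    full[names(mapping)] <- unname(mapping)
  }
  if (!default_identity) {
    missing <- setdiff(source_labels, names(mapping))
    if (length(missing))
      stop("mapping not total; missing: ", paste(missing, collapse = ", "))
  }
  structure(list(name = name, mapping = full,
                 labels = sort(unique(unname(full[full != "DELETE"])))),
            class = "class_scheme")
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("<class_scheme> ", x$name, ": ", length(x$mapping), " source labels -> ",
      length(x$labels), " labels (",
      sum(x$mapping == "DELETE"), " deleted)\n", sep = "")
  invisible(x)
}

.name_refinements <- c("Clinician_First_Name", "Patient_First_Name",
                       "Relative_First_Name")
.name_refinements_last <- c("Clinician_Last_Name", "Patient_Last_Name",
                            "Relative_Last_Name")
.infrequent <- c("E-mail_Address", "Social_Security_Number",
                 "Medical_Record_Number", "Profession", "URL", "ID_Number",
                 "Relation", "Ethnicity")

build_scheme_registry <- function() {
  del <- function(labs) setNames(rep("DELETE", length(labs)), labs)
  to <- function(labs, target) setNames(rep(target, length(labs)), labs)
  m2 <- del(.infrequent)
  m3 <- c(m2, to(c("Clinician_First_Name", "Patient_First_Name"), "First_Name"),
          to(c("Clinician_Last_Name", "Patient_Last_Name"), "Last_Name"))
  m4 <- c(m3, to(.name_refinements, "First_Name"),
          to(.name_refinements_last, "Last_Name"),
          Age_Over_89 = "Age")
  m5 <- c(m4, to(c("First_Name", "Last_Name", .name_refinements,
                   .name_refinements_last), "Name"))
  m6 <- c(m5, to(c("Street_Address", "Town", "Municipality", "Country",
                   "Organization"), "Location"),
          Full_Date = "Date", Date_Part = "Date")
  m7 <- setNames(rep("PHI", length(.catalog_labels)), .catalog_labels)
  manual <- c(to(.name_refinements, "First_Name"),
              to(.name_refinements_last, "Last_Name"),
              Age_Over_89 = "Age",
              to(c("Street_Address", "Town", "Municipality", "Country",
                   "Organization"), "Location"),
              del(c("Relation", "Ethnicity")))
  list(
    full_28 = class_scheme("full_28", character()),
    auto_2 = class_scheme("auto_2", m2),
    auto_3 = class_scheme("auto_3", m3),
    auto_4 = class_scheme("auto_4", m4),
    auto_5 = class_scheme("auto_5", m5),
    auto_6 = class_scheme("auto_6", m6),
    phi_1 = class_scheme("phi_1", m7),
    manual_gs = class_scheme("manual_gs", manual)
  )
}

.scheme_registry <- NULL

#' Retrieve a registered class scheme
#'
#' Registered names: `full_28` (identity on the catalog), `auto_2` ...
#' `auto_6` (progressive merges; `auto_3` has 16 classes and `auto_4` 13),
#' `phi_1` (everything into one `PHI` class), and `manual_gs` (the
#' manually refined consensus label set: generic names, `Age`, both date
#' classes, `Location`, `Health_Care_Unit`, `Phone_Number`; `Relation` and
#' `Ethnicity` deleted).
#'
#' @param name scheme name.
#' @return An immutable `class_scheme`.
#' @examples
#' get_scheme("phi_1")$labels
#' length(get_scheme("auto_4")$labels)
#' @export
get_scheme <- function(name) {
  reg <- scheme_registry()
  if (!name %in% names(reg))
    stop("unknown scheme ", dQuote(name), "; available: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

scheme_registry <- function() {
  if (is.null(.scheme_registry))
    utils::assignInMyNamespace(".scheme_registry", build_scheme_registry())
  .scheme_registry
}

#' @describeIn get_scheme Names of all registered schemes, in experiment
#'   order.
#' @export
list_schemes <- function() names(scheme_registry())

#' Apply a class scheme to an annotation set
#'
#' Spans are unchanged; labels are mapped; annotations whose class maps to
#' `DELETE` are removed.  The count is conserved minus deletions.
#'
#' @param set an [annotation_set()].
#' @param scheme a `class_scheme` (or a registered scheme name).
#' @return The mapped [annotation_set()].
#' @export
apply_scheme <- function(set, scheme) {
  if (is.character(scheme)) scheme <- get_scheme(scheme)
  stopifnot(inherits(scheme, "class_scheme"))
  df <- as.data.frame(set)
  if (!nrow(df)) return(set)
  unmapped <- setdiff(unique(df$label), names(scheme$mapping))
  if (length(unmapped))
    stop("labels not covered by scheme ", scheme$name, ": ",
         paste(unmapped, collapse = ", "))
  df$label <- unname(scheme$mapping[df$label])
  annotation_set(df[df$label != "DELETE", , drop = FALSE], validate = FALSE)
}

#' @param a,b two `class_scheme`s; `b` is applied after `a`.
#' @describeIn apply_scheme Scheme composition: `compose_schemes(a, b)`
#'   equals applying `a` then `b` (deletions propagate).
#' @export
compose_schemes <- function(a, b) {
  mapping <- vapply(a$mapping, function(t) {
    if (t == "DELETE") "DELETE"
    else if (t %in% names(b$mapping)) unname(b$mapping[[t]])
    else t
  }, character(1))
  structure(list(name = paste0(b$name, ".", a$name), mapping = mapping,
                 labels = sort(unique(unname(mapping[mapping != "DELETE"])))),
            class = "class_scheme")
}

#' @param path YAML/JSON file: a map of source label -> target (or DELETE).
#' @param name scheme name for the loaded mapping.
#' @describeIn get_scheme Load a scheme from a YAML mapping file.
#' @export
read_scheme <- function(path, name = basename(path)) {
  cfg <- yaml::read_yaml(path)
  class_scheme(name, unlist(cfg))
}
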