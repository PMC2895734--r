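#' PHI label catalogs and the label-specificity order
#'
#' A label catalog is the set of PHI class names in play plus a specificity
#' relation mapping each *specific* label to exactly one *generic* parent
#' (e.g. `Clinician_First_Name` is a specific kind of `First_Name`).  The
#' relation drives class-mismatch resolution in the automatic consensus
#' builder: when two annotators label the same instance with comparable
#' classes, the more specific one wins.
#'
#' @param labels character vector of PHI class names.
#' @param specificity named character vector mapping specific label ->
#'   generic parent label.  Must be acyclic; each specific label has exactly
#'   one parent.
#' @return An object of class `label_catalog` with elements `labels` and
#'   `specificity`.
#' @examples
#' cat28 <- default_catalog()
#' "Health_Care_Unit" %in% cat28$labels
#' @export
label_catalog <- function(labels, specificity = character()) {
  labels <- as.character(labels)
  stopifnot(!anyDuplicated(labels), all(nzchar(labels)))
  if (length(specificity)) {
    stopifnot(!is.null(names(specificity)),
              all(names(specificity) %in% labels),
              all(specificity %in% labels))
    # acyclicity: walking parents from any label must terminate
    for (l in names(specificity)) {
      seen <- character()
      cur <- l
      while (cur %in% names(specificity)) {
        if (cur %in% seen) stop("specificity relation contains a cycle at ", cur)
        seen <- c(seen, cur)
        cur <- unname(specificity[[cur]])
      }
    }
  }
  structure(list(labels = labels, specificity = specificity),
            class = "label_catalog")
}

#' @export
print.label_catalog <- function(x, ...) {
  cat("<label_catalog> ", length(x$labels), " labels, ",
      length(x$specificity), " specificity pairs\n", sep = "")
  cat(strwrap(paste(x$labels, collapse = ", "), indent = 2, exdent = 2),
      sep = "\n")
  invisible(x)
}

# Pre-refinement 28-label catalog.  The classes named in the source study
# (name refinements, ages, dates, the five pre-merge location classes,
# Relation, Ethnicity, contact/identifier classes) are completed with four
# conventional HIPAA-style identifier classes; the full historical roster is
# unpublished, so this default is a documented reconstruction, not canon.
.catalog_labels <- c(
  "First_Name", "Last_Name",
  "Clinician_First_Name", "Clinician_Last_Name",
  "Patient_First_Name", "Patient_Last_Name",
  "Relative_First_Name", "Relative_Last_Name",
  "Age", "Age_Over_89",
  "Full_Date", "Date_Part",
  "Street_Address", "Town", "Municipality", "Country", "Organization",
  "Location", "Health_Care_Unit", "Phone_Number",
  "E-mail_Address", "Social_Security_Number", "Medical_Record_Number",
  "Profession", "URL", "ID_Number", "Relation", "Ethnicity"
)

.catalog_specificity <- c(
  Clinician_First_Name = "First_Name", Patient_First_Name = "First_Name",
  Relative_First_Name = "First_Name",
  Clinician_Last_Name = "Last_Name", Patient_Last_Name = "Last_Name",
  Relative_Last_Name = "Last_Name",
  Age_Over_89 = "Age",
  Street_Address = "Location", Town = "Location", Municipality = "Location",
  Country = "Location", Organization = "Location"
)

#' @describeIn label_catalog The default pre-refinement 28-class catalog,
#'   including the `Clinician_`/`Patient_`/`Relative_` name refinements,
#'   `Age_Over_89`, and the five location classes later merged into
#'   `Location`.
#' @export
default_catalog <- function() {
  label_catalog(.catalog_labels, .catalog_specificity)
}

#' @describeIn label_catalog The post-refinement catalog: the class set
#'   proposed for future annotation work (generic names, `Age`, the two date
#'   classes, `Location`, `Health_Care_Unit`, `Phone_Number`,
#'   `E-mail_Address`, `Social_Security_Number`).
#' @export
refined_catalog <- function() {
  label_catalog(c("Age", "First_Name", "Last_Name", "Date_Part", "Full_Date",
                  "Location", "Health_Care_Unit", "Phone_Number",
                  "E-mail_Address", "Social_Security_Number"))
}

# TRUE iff a is an ancestor of b (b more specific), or a == b.
label_is_ancestor <- function(a, b, catalog) {
  cur <- b
  repeat {
    if (identical(cur, a)) return(TRUE)
    if (!cur %in% names(catalog$specificity)) return(FALSE)
    cur <- unname(catalog$specificity[[cur]])
  }
}

# depth of a label in the specificity forest (generic roots have depth 0)
label_depth <- function(l, catalog) {
  d <- 0L
  while (l %in% names(catalog$specificity)) {
    l <- unname(catalog$specificity[[l]])
    d <- d + 1L
  }
  d
}
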