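# Canonical factor levels shared across the package.
.carafa_levels <- list(
  sex        = c("F", "M"),
  wing_morph = c("A", "B", "M"),
  treatment  = c("clearing", "control", "ecotone"),
  trap_type  = c("pitfall", "emergence"),
  side       = c("L", "R"),
  trait      = c("f_femur", "f_tibia", "h_femur", "metatrochanter",
                 "a2", "a3", "a4", "pm2", "pm3l", "pm3w",
                 "head_width", "elytron_r")
)

#' Numeric score for wing morphology
#'
#' Wing morphs are ordered by dispersal ability and enter regression models
#' as a numeric score: apterous (A) = 1, brachypterous (B) = 2,
#' macropterous (M) = 3.
#'
#' @param morph character vector of codes `"A"`, `"B"`, `"M"`.
#' @return integer vector of scores 1/2/3.
#' @export
#' @examples
#' wing_morph_score(c("A", "M", "B"))
wing_morph_score <- function(morph) {
  out <- match(morph, .carafa_levels$wing_morph)
  if (anyNA(out[!is.na(morph)])) {
    bad <- unique(morph[!morph %in% .carafa_levels$wing_morph & !is.na(morph)])
    stop("unknown wing morph code(s): ", paste(bad, collapse = ", "))
  }
  out
}

.read_table <- function(path, delim = ",", char_cols = character(0)) {
  # key/enum columns are forced to character: codes like "F" (female) or
  # "T" (a species acronym) must never be parsed as logicals
  cc <- if (length(char_cols) > 0)
    setNames(rep("character", length(char_cols)), char_cols) else NA
  utils::read.table(path, header = TRUE, sep = delim,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = cc, strip.white = FALSE)
}

.require_cols <- function(df, cols, what, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " (", path, "): missing column(s) ",
         paste(missing, collapse = ", "))
  }
}

.check_enum <- function(values, levels, what, col) {
  bad <- which(!values %in% levels & !is.na(values))
  if (length(bad) > 0) {
    stop(what, ": unknown ", col, " level ",
         sQuote(values[bad[1]]), " at row ", bad[1])
  }
  invisible(TRUE)
}

#' Load a carabid dataset from delimited text files
#'
#' Reads the five standard tables (individual records, replicated bilateral
#' measurements, sample-by-species community matrix, sample-by-environment
#' table, species identity traits), resolves cross-table keys and returns a
#' single `carabid_dataset` object. Unknown enum levels (e.g. a wing-morph
#' code outside A/B/M) are fatal with the offending row reported; unresolved
#' foreign keys are collected into the attached validation report rather
#' than silently dropped.
#'
#' @param individuals,measurements,community,environment,species_traits
#'   file paths; any may be `NULL` to omit that table.
#' @param delim field delimiter, default comma.
#' @return a `carabid_dataset`: list of data frames `individuals`,
#'   `measurements`, `community` (matrix, samples x species),
#'   `environment`, `species_traits`, with a [validate_dataset()] report in
#'   attribute `"validation"`.
#' @seealso [validate_dataset()], [write_results()]
#' @export
load_dataset <- function(individuals = NULL, measurements = NULL,
                         community = NULL, environment = NULL,
                         species_traits = NULL, delim = ",") {
  paths <- list(individuals = individuals, measurements = measurements,
                community = community, environment = environment,
                species_traits = species_traits)
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]])) {
      stop("file not found for ", nm, ": ", paths[[nm]])
    }
  }
  d <- list(individuals = NULL, measurements = NULL, community = NULL,
            environment = NULL, species_traits = NULL)

  if (!is.null(individuals)) {
    ind <- .read_table(individuals, delim,
                       char_cols = c("individual_id", "species", "sex",
                                     "wing_morph", "treatment", "site_id",
                                     "trap_type"))
    .require_cols(ind, c("individual_id", "species", "sex", "wing_morph",
                         "treatment", "site_id", "month", "trap_type",
                         "body_size"), "individuals", individuals)
    ind$individual_id <- as.character(ind$individual_id)
    ind$species <- as.character(ind$species)
    if (nrow(ind) > 0) {
      .check_enum(ind$sex, .carafa_levels$sex, "individuals", "sex")
      .check_enum(ind$wing_morph, .carafa_levels$wing_morph,
                  "individuals", "wing_morph")
      .check_enum(ind$treatment, .carafa_levels$treatment,
                  "individuals", "treatment")
      .check_enum(ind$trap_type, .carafa_levels$trap_type,
                  "individuals", "trap_type")
      ind$wing_score <- wing_morph_score(ind$wing_morph)
    } else {
      ind$wing_score <- integer(0)
    }
    d$individuals <- ind
  }
  if (!is.null(measurements)) {
    m <- .read_table(measurements, delim,
                     char_cols = c("individual_id", "trait", "side"))
    .require_cols(m, c("individual_id", "trait", "side", "replicate",
                       "value"), "measurements", measurements)
    m$individual_id <- as.character(m$individual_id)
    m$trait <- as.character(m$trait)
    if (nrow(m) > 0) {
      .check_enum(m$side, .carafa_levels$side, "measurements", "side")
      .check_enum(as.character(m$replicate), c("1", "2"),
                  "measurements", "replicate")
    }
    d$measurements <- m
  }
  if (!is.null(community)) {
    com <- .read_table(community, delim)
    if (ncol(com) < 1) stop("community matrix has no columns")
    rn <- as.character(com[[1]])
    com <- as.matrix(com[, -1, drop = FALSE])
    storage.mode(com) <- "double"
    rownames(com) <- rn
    d$community <- com
  }
  if (!is.null(environment)) {
    env <- .read_table(environment, delim,
                       char_cols = c("sample_id", "treatment"))
    .require_cols(env, c("sample_id", "herbs", "canopy_openness", "litter",
                         "air_temp", "soil_moisture", "collembola",
                         "formica", "treatment"), "environment", environment)
    env$sample_id <- as.character(env$sample_id)
    if (nrow(env) > 0) {
      .check_enum(env$treatment, .carafa_levels$treatment,
                  "environment", "treatment")
    }
    d$environment <- env
  }
  if (!is.null(species_traits)) {
    st <- .read_table(species_traits, delim,
                      char_cols = c("species", "ecological_valence",
                                    "dietary_preference"))
    .require_cols(st, c("species", "ecological_valence",
                        "dietary_preference"), "species_traits",
                  species_traits)
    st$species <- as.character(st$species)
    d$species_traits <- st
  }
  class(d) <- "carabid_dataset"
  attr(d, "validation") <- validate_dataset(d)
  d
}

#' Assemble a carabid dataset from in-memory tables
#'
#' Programmatic counterpart of [load_dataset()] used by the simulators and
#' tests.
#'
#' @param individuals,measurements data frames (may be `NULL`).
#' @param community numeric matrix samples x species (may be `NULL`).
#' @param environment,species_traits data frames (may be `NULL`).
#' @return a `carabid_dataset`.
#' @export
carabid_dataset <- function(individuals = NULL, measurements = NULL,
                            community = NULL, environment = NULL,
                            species_traits = NULL) {
  d <- list(individuals = individuals, measurements = measurements,
            community = community, environment = environment,
            species_traits = species_traits)
  if (!is.null(d$individuals) && !"wing_score" %in% names(d$individuals)) {
    d$individuals$wing_score <- wing_morph_score(d$individuals$wing_morph)
  }
  class(d) <- "carabid_dataset"
  d
}

#' @export
print.carabid_dataset <- function(x, ...) {
  cat("carabid_dataset\n")
  if (!is.null(x$individuals))
    cat("  individuals:   ", nrow(x$individuals), " records, ",
        length(unique(x$individuals$species)), " species\n", sep = "")
  if (!is.null(x$measurements))
    cat("  measurements:  ", nrow(x$measurements), " rows\n", sep = "")
  if (!is.null(x$community))
    cat("  community:     ", nrow(x$community), " samples x ",
        ncol(x$community), " species\n", sep = "")
  if (!is.null(x$environment))
    cat("  environment:   ", nrow(x$environment), " samples\n", sep = "")
  if (!is.null(x$species_traits))
    cat("  species traits:", nrow(x$species_traits), "species\n")
  invisible(x)
}

.vr_entry <- function(severity, message, keys = character(0)) {
  list(severity = severity, message = message, keys = keys)
}

#' Validate a carabid dataset
#'
#' Enforces the structural invariants of every table: positive finite body
#' sizes and measurement values, legal factor levels, percentages within
#' [0, 100], non-negative abundances, unique keys, exactly two replicates
#' per (individual, trait, side), and resolvable foreign keys between the
#' measurement and individual tables. The check is side-effect free and
#' idempotent; findings are returned, never thrown.
#'
#' @param d a `carabid_dataset`.
#' @return a `validation_report`: list with `entries` (each a list of
#'   severity, message, offending keys) and logical `pass` (`FALSE` iff at
#'   least one error-severity entry).
#' @export
validate_dataset <- function(d) {
  stopifnot(inherits(d, "carabid_dataset"))
  entries <- list()
  add <- function(e) entries[[length(entries) + 1L]] <<- e

  ind <- d$individuals
  if (!is.null(ind)) {
    if (nrow(ind) == 0) add(.vr_entry("warning", "individuals: no rows"))
    if (nrow(ind) > 0) {
      if (anyDuplicated(ind$individual_id))
        add(.vr_entry("error", "duplicate individual_id",
                      unique(ind$individual_id[duplicated(ind$individual_id)])))
      bad <- ind$individual_id[!is.finite(ind$body_size) | ind$body_size <= 0]
      if (length(bad) > 0)
        add(.vr_entry("error", "body_size must be finite and positive", bad))
      bad <- ind$individual_id[!ind$month %in% 1:12]
      if (length(bad) > 0)
        add(.vr_entry("error", "month outside 1..12", bad))
      if (!all(ind$wing_score %in% 1:3))
        add(.vr_entry("error", "wing morph numeric coding outside 1/2/3"))
    }
  }

  m <- d$measurements
  if (!is.null(m)) {
    if (nrow(m) == 0) add(.vr_entry("warning", "measurements: no rows"))
    if (nrow(m) > 0) {
      bad <- which(!is.finite(m$value) | m$value <= 0)
      if (length(bad) > 0)
        add(.vr_entry("error", "measurement values must be finite and positive",
                      paste(m$individual_id[bad], m$trait[bad], sep = ":")))
      cnt <- stats::aggregate(replicate ~ individual_id + trait + side,
                              data = m, FUN = length)
      off <- cnt[cnt$replicate != 2L, , drop = FALSE]
      if (nrow(off) > 0)
        add(.vr_entry("error",
                      "each (individual, trait, side) needs exactly 2 replicates",
                      paste(off$individual_id, off$trait, off$side, sep = ":")))
      if (!is.null(ind) && nrow(ind) > 0) {
        orphan <- setdiff(unique(m$individual_id), ind$individual_id)
        if (length(orphan) > 0)
          add(.vr_entry("error",
                        "measurements reference unknown individual_id", orphan))
      }
    }
  }

  com <- d$community
  if (!is.null(com)) {
    if (nrow(com) == 0) add(.vr_entry("warning", "community: no rows"))
    if (any(com < 0))
      add(.vr_entry("error", "negative abundance cell(s)",
                    rownames(com)[which(com < 0, arr.ind = TRUE)[, 1]]))
    if (anyDuplicated(rownames(com)))
      add(.vr_entry("error", "duplicate community sample keys"))
    if (anyDuplicated(colnames(com)))
      add(.vr_entry("error", "duplicate community species codes"))
  }

  env <- d$environment
  if (!is.null(env) && nrow(env) > 0) {
    if (anyDuplicated(env$sample_id))
      add(.vr_entry("error", "duplicate environment sample_id"))
    for (pc in c("herbs", "canopy_openness")) {
      bad <- env$sample_id[env[[pc]] < 0 | env[[pc]] > 100]
      if (length(bad) > 0)
        add(.vr_entry("error", paste0(pc, " outside [0, 100]"), bad))
    }
    for (nn in c("litter", "soil_moisture", "collembola", "formica")) {
      bad <- env$sample_id[env[[nn]] < 0]
      if (length(bad) > 0)
        add(.vr_entry("error", paste0(nn, " negative"), bad))
    }
    if (!is.null(com)) {
      orphan <- setdiff(rownames(com), env$sample_id)
      if (length(orphan) > 0)
        add(.vr_entry("warning", "community samples without environment row",
                      orphan))
    }
  }

  st <- d$species_traits
  if (!is.null(st) && !is.null(com) && ncol(com) > 0) {
    missing_sp <- setdiff(colnames(com), st$species)
    if (length(missing_sp) > 0)
      add(.vr_entry("error", "community species missing from species_traits",
                    missing_sp))
  }

  pass <- !any(vapply(entries, function(e) e$severity == "error", logical(1)))
  structure(list(entries = entries, pass = pass),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation:", if (x$pass) "PASS" else "FAIL", "\n")
  for (e in x$entries) {
    cat("  [", e$severity, "] ", e$message, sep = "")
    if (length(e$keys) > 0)
      cat(" (", paste(utils::head(e$keys, 5), collapse = ", "),
          if (length(e$keys) > 5) ", ..." else "", ")", sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Write a result object to disk
#'
#' Flat tables go to delimited text (round-trip safe via [utils::read.table]);
#' lists go to JSON. The written file reads back field-wise equal.
#'
#' @param obj data frame, matrix, or list.
#' @param path output file path (`.csv`/`.tsv` for tables, `.json` for lists).
#' @param delim delimiter for tabular output.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path, delim = ",") {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (is.matrix(obj)) {
    obj <- data.frame(sample_id = rownames(obj), obj, check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  if (is.data.frame(obj)) {
    ok <- tryCatch({
      utils::write.table(obj, path, sep = delim, row.names = FALSE,
                         quote = TRUE, qmethod = "double")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("could not write results to ", path)
  } else if (is.list(obj)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else {
    stop("write_results: unsupported object of class ", class(obj)[1])
  }
  invisible(path)
}

#' Write all five dataset tables to a directory
#'
#' @param d a `carabid_dataset`.
#' @param dir output directory (created if needed).
#' @param delim delimiter.
#' @return named character vector of file paths, invisibly.
#' @export
write_dataset <- function(d, dir, delim = ",") {
  stopifnot(inherits(d, "carabid_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- c()
  tabs <- list(individuals = d$individuals, measurements = d$measurements,
               environment = d$environment, species_traits = d$species_traits)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    t <- tabs[[nm]]
    t$wing_score <- NULL
    p <- file.path(dir, paste0(nm, ".csv"))
    write_results(t, p, delim)
    out[nm] <- p
  }
  if (!is.null(d$community)) {
    p <- file.path(dir, "community.csv")
    write_results(d$community, p, delim)
    out["community"] <- p
  }
  invisible(out)
}
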