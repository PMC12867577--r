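#' Per-animal metadata: loading, harmonization, annotation
#'
#' Metabolic-cage studies annotate each animal with grouping factors
#' (genotype, sex, diet, treatment, ...), body mass, and the photoperiod of
#' the animal facility. Multi-cohort studies rarely agree on labels
#' ("KO" vs "knockout", "Genotype" vs "genotype "), so the metadata module
#' harmonizes factor names and levels into one internal vocabulary before any
#' joint analysis.
#'
#' @name metadata
NULL

# Built-in synonym core: canonical label -> aliases (all compared after
# trim + case-fold). User dictionaries extend/override via harmonize_labels().
CK_BUILTIN_SYNONYMS <- list(
  animal_id = c("animal id", "animal_id", "animal", "id", "box", "subject",
                "subject id", "animal no.", "mouse id"),
  body_mass = c("body mass", "body_mass", "bodymass", "body weight",
                "bodyweight", "bw", "weight", "mass"),
  lean_mass = c("lean mass", "lean_mass", "leanmass", "lean"),
  genotype = c("genotype", "gt", "strain"),
  sex = c("sex", "gender"),
  diet = c("diet", "food type"),
  treatment = c("treatment", "condition", "trt"),
  cohort_id = c("cohort", "cohort id", "cohort_id", "study"),
  knockout = c("knockout", "ko", "k.o.", "k.o", "kn.-out"),
  wildtype = c("wildtype", "wild-type", "wild type", "wt", "+/+"),
  male = c("male", "m"),
  female = c("female", "f"),
  lights_on = c("lights on", "lights_on", "light on", "lighton"),
  lights_off = c("lights off", "lights_off", "light off", "lightoff")
)

canon_fold <- function(x) tolower(trimws(x))

lookup_synonym <- function(x, dict) {
  key <- canon_fold(x)
  for (canonical in names(dict))
    if (key %in% canon_fold(dict[[canonical]]) || key == canonical)
      return(canonical)
  NA_character_
}

#' Load a per-animal metadata sheet
#'
#' Reads a tabular metadata sheet (CSV; one row per animal). The animal-id
#' column is located via the built-in alias list ("Animal ID", "Animal",
#' "ID", "Box", ...). Known quantitative columns (body mass, lean mass)
#' become numeric fields — decimal commas are accepted; every other column
#' becomes a grouping factor. Photoperiod columns (lights on / lights off
#' clock times) are captured when present.
#'
#' @param path CSV file, one row per animal.
#' @param sep field separator; default auto-detects "," vs ";".
#' @return a \code{metadata_table}: data.frame with \code{animal_id},
#'   optional \code{cohort_id}, \code{body_mass}, \code{lean_mass}, factor
#'   columns, and a \code{"photoperiod"} attribute when the sheet defines one.
#' @export
load_metadata_sheet <- function(path, sep = NULL) {
  if (!file.exists(path)) ck_stop("metadata sheet not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (is.null(sep))
    sep <- if (lengths(regmatches(first, gregexpr(";", first))) >
               lengths(regmatches(first, gregexpr(",", first)))) ";" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  cols <- names(tab)
  roles <- vapply(cols, lookup_synonym, character(1),
                  dict = CK_BUILTIN_SYNONYMS[c("animal_id", "cohort_id",
                                               "body_mass", "lean_mass",
                                               "lights_on", "lights_off")])
  id_col <- cols[which(roles == "animal_id")]
  if (!length(id_col)) ck_stop("metadata sheet has no animal-id column ",
                               "(accepted: Animal ID, Animal, ID, Box, ...)")
  id_col <- id_col[1]
  out <- data.frame(animal_id = trimws(tab[[id_col]]))
  if (anyDuplicated(out$animal_id))
    ck_stop("duplicate animal id(s) in metadata sheet: ",
            paste(unique(out$animal_id[duplicated(out$animal_id)]),
                  collapse = ", "))
  photoperiod <- NULL
  for (i in seq_along(cols)) {
    if (cols[i] == id_col) next
    role <- roles[i]
    if (identical(role, "cohort_id")) {
      out$cohort_id <- trimws(tab[[i]])
    } else if (role %in% c("body_mass", "lean_mass")) {
      # decimal commas are common in European sheets
      mark <- if (any(grepl(",", tab[[i]], fixed = TRUE))) "," else "."
      out[[role]] <- parse_num(tab[[i]], mark)
    } else if (role %in% c("lights_on", "lights_off")) {
      photoperiod[[role]] <- trimws(tab[[i]][1])
    } else {
      out[[cols[i]]] <- trimws(tab[[i]])
    }
  }
  if (!is.null(photoperiod$lights_on) && !is.null(photoperiod$lights_off))
    attr(out, "photoperiod") <- photoperiod(photoperiod$lights_on,
                                            photoperiod$lights_off)
  class(out) <- c("metadata_table", "data.frame")
  out
}

metadata_factor_cols <- function(meta) {
  setdiff(names(meta), c("animal_id", "cohort_id", "body_mass", "lean_mass"))
}

#' Harmonize metadata labels across cohorts
#'
#' Unifies factor names and factor levels across one or more metadata tables:
#' (1) trim + case-fold, (2) built-in and user synonym dictionaries,
#' (3) explicit user overrides (which win over everything and are logged as
#' such). Returns the merged table plus a harmonization map recording every
#' applied rule; applying the function to its own output is the identity.
#'
#' @param tables a \code{metadata_table} or list of them.
#' @param synonyms optional named list: canonical label -> character vector of
#'   aliases (extends the built-in dictionary).
#' @param overrides optional named character vector: raw label -> canonical
#'   label, applied last and logged as \code{user_override}.
#' @return list with \code{metadata} (merged harmonized table) and \code{map}
#'   (data.frame: raw_label, canonical_label, rule).
#' @export
harmonize_labels <- function(tables, synonyms = list(), overrides = c()) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  dict <- CK_BUILTIN_SYNONYMS
  for (nm in names(synonyms))
    dict[[nm]] <- unique(c(dict[[nm]], synonyms[[nm]]))

  map <- data.frame(raw_label = character(0), canonical_label = character(0),
                    rule = character(0))
  remember <- function(raw, canonical, rule) {
    if (!raw %in% map$raw_label)
      map[nrow(map) + 1L, ] <<- list(raw, canonical, rule)
    canonical
  }
  canonize <- function(raw) {
    ov <- overrides[names(overrides) == raw]
    if (length(ov)) return(remember(raw, unname(ov[1]), "user_override"))
    folded <- canon_fold(raw)
    hit <- lookup_synonym(raw, dict)
    if (!is.na(hit) && hit != folded)
      return(remember(raw, hit, "synonym"))
    if (!is.na(hit)) return(remember(raw, hit, if (folded == raw) "exact"
                                     else "case_fold"))
    remember(raw, folded, if (folded == raw) "exact" else "case_fold")
  }

  merged <- list()
  for (tb in tables) {
    df <- as.data.frame(tb)
    fac <- metadata_factor_cols(df)
    new_names <- names(df)
    for (f in fac) {
      cn <- canonize(f)
      new_names[new_names == f] <- cn
      df[[f]] <- vapply(as.character(df[[f]]), canonize, character(1),
                        USE.NAMES = FALSE)
    }
    if (anyDuplicated(new_names))
      ck_stop("harmonization collapses two distinct factors to one name: ",
              paste(unique(new_names[duplicated(new_names)]), collapse = ", "))
    names(df) <- new_names
    merged[[length(merged) + 1L]] <- df
  }
  all_cols <- unique(unlist(lapply(merged, names)))
  merged <- lapply(merged, function(d) {
    d[setdiff(all_cols, names(d))] <- NA
    d[all_cols]
  })
  out <- do.call(rbind, c(merged, make.row.names = FALSE))
  if (anyDuplicated(paste(out$cohort_id %||% "", out$animal_id)))
    ck_stop("duplicate animal id(s) after merging metadata tables")
  pp <- Filter(Negate(is.null), lapply(tables, attr, "photoperiod"))
  if (length(pp)) attr(out, "photoperiod") <- pp[[1]]
  class(out) <- c("metadata_table", "data.frame")
  list(metadata = out, map = map)
}

#' Annotate a calorimetry frame with per-animal metadata
#'
#' Joins harmonized factor columns and body mass onto every sample row.
#' Animals present in the frame but absent from the metadata are retained
#' with missing factor values and reported via a warning; measurement values
#' and row count are never altered.
#'
#' @param frame a [calorimetry_frame()].
#' @param meta a harmonized \code{metadata_table}.
#' @return the annotated frame.
#' @export
apply_metadata <- function(frame, meta) {
  if (is.null(meta) || !nrow(meta)) {
    ck_warn("empty metadata: frame left unannotated")
    return(frame)
  }
  missing_ids <- setdiff(unique(frame$animal_id), meta$animal_id)
  if (length(missing_ids))
    ck_warn("animal(s) missing from metadata, kept with missing factors: ",
            paste(missing_ids, collapse = ", "))
  add_cols <- setdiff(names(meta), c("animal_id", "cohort_id"))
  idx <- match(frame$animal_id, meta$animal_id)
  at <- attributes(frame)
  for (col in add_cols) frame[[col]] <- meta[[col]][idx]
  for (nm in setdiff(names(at), c("names", "row.names", "class")))
    attr(frame, nm) <- at[[nm]]
  if (!is.null(attr(meta, "photoperiod")))
    attr(frame, "photoperiod") <- attr(meta, "photoperiod")
  frame
}

#' Photoperiod of the animal facility
#'
#' @param lights_on,lights_off clock times ("HH:MM" or fractional hours).
#' @return a \code{photoperiod} object.
#' @export
photoperiod <- function(lights_on = "07:00", lights_off = "19:00") {
  on <- clock_hours(lights_on)
  off <- clock_hours(lights_off)
  if (isTRUE(all.equal(on, off)))
    ck_stop("lights_on and lights_off must differ")
  structure(list(lights_on = on, lights_off = off,
                 dark_onset = (off - on) %% 24),
            class = "photoperiod")
}

#' @export
print.photoperiod <- function(x, ...) {
  cat(sprintf("<photoperiod> lights on %05.2fh, off %05.2fh (dark onset ZT%g)\n",
              x$lights_on, x$lights_off, x$dark_onset))
  invisible(x)
}

# Fallback used by pipeline stages that need a photoperiod but got none.
default_photoperiod <- function() {
  ck_warn("no photoperiod defined anywhere; assuming 12:12 with lights on ",
          "07:00 — specify the true photoperiod in the metadata sheet or ",
          "manually")
  photoperiod("07:00", "19:00")
}

#' Zeitgeber time of a timestamp
#'
#' Converts clock timestamps to zeitgeber time: hours since lights-on, in
#' [0, 24). ZT0 is light onset; the light phase spans [0, dark_onset) and the
#' dark phase [dark_onset, 24), where dark_onset is the photoperiod's
#' lights-on to lights-off distance.
#'
#' @param timestamp POSIXct vector (or "HH:MM" clock strings).
#' @param pp a [photoperiod()].
#' @return numeric vector of ZT hours; the light/dark phase is available via
#'   [zt_phase()].
#' @export
zeitgeber_time <- function(timestamp, pp) {
  if (is.null(pp)) ck_stop("photoperiod undefined: supply one via the ",
                           "metadata sheet or specify it manually")
  hrs <- if (inherits(timestamp, "POSIXct")) {
    lt <- as.POSIXlt(timestamp, tz = CK_TZ)
    lt$hour + lt$min / 60 + lt$sec / 3600
  } else clock_hours(timestamp)
  (hrs - pp$lights_on) %% 24
}

#' @rdname zeitgeber_time
#' @param zt zeitgeber hours as returned by \code{zeitgeber_time}.
#' @export
zt_phase <- function(zt, pp) {
  ifelse(zt < pp$dark_onset, "light", "dark")
}
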