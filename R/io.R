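#' Read a peptide-level HDX state table
#'
#' Reads peptide centroid observations from CSV into a [StateTable-class].
#' Two dialects are supported. `"native"` is this package's own long format
#' with columns `protein, start, end, sequence, condition, exposure, m0, mt,
#' mmaxD, replicate` (exposure in seconds or time tokens such as `"1 min"`;
#' see [parseExposure()]). `"dynamx"` reads a DynamX-style state-data export
#' with columns `Protein, Start, End, Sequence, State, Exposure, Center`:
#' the undeuterated centroid `m0` is taken from each peptide's
#' zero-exposure rows and the maxD control from rows whose state matches
#' `maxdState`.
#'
#' Rows with a blank observed centroid are kept as records flagged missing
#' (`mt = NA`); they are never imputed. When `proteins` are supplied, every
#' record's peptide sequence is validated against the protein sequence at
#' its stated interval.
#'
#' @param path CSV file path
#' @param dialect `"native"` or `"dynamx"`
#' @param proteins optional list of [ProteinEntry-class] to attach and
#'   validate against
#' @param maxdState state label identifying maximally deuterated control
#'   rows in the dynamx dialect
#' @return a [StateTable-class]
#' @seealso [writePeptideStateTable()]
#' @export
readPeptideStateTable <- function(path, dialect = c("native", "dynamx"),
                                  proteins = list(), maxdState = "maxD") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopUsage("file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  req <- if (dialect == "native") .state_cols else
    c("protein", "start", "end", "sequence", "state", "exposure", "center")
  missing <- setdiff(if (dialect == "native")
    setdiff(req, c("mmaxD", "replicate")) else req, names(df))
  if (length(missing))
    stopUsage("state table is missing required column(s): ",
              paste(missing, collapse = ", "))
  if (dialect == "native") {
    if (is.null(df$mmaxd) && is.null(df$mmaxD)) df$mmaxd <- NA_real_
    if (is.null(df$replicate)) df$replicate <- 1L
    rec <- data.frame(
      protein = as.character(df$protein),
      start = as.integer(df$start), end = as.integer(df$end),
      sequence = toupper(as.character(df$sequence)),
      condition = as.character(df$condition),
      exposure = parseExposure(df$exposure),
      m0 = as.numeric(df$m0), mt = as.numeric(df$mt),
      mmaxD = as.numeric(df$mmaxd),
      replicate = as.integer(df$replicate),
      stringsAsFactors = FALSE)
  } else {
    df$exposure <- parseExposure(df$exposure)
    df$center <- suppressWarnings(as.numeric(df$center))
    key <- paste(df$protein, df$start, df$end, df$sequence)
    isMax <- df$state == maxdState
    maxd <- tapply(df$center[isMax], key[isMax], mean, na.rm = TRUE)
    zero <- !isMax & df$exposure == 0
    m0 <- tapply(df$center[zero], key[zero], mean, na.rm = TRUE)
    keep <- !isMax & df$exposure > 0
    if (is.null(df$file)) df$file <- ""
    rec <- data.frame(
      protein = as.character(df$protein[keep]),
      start = as.integer(df$start[keep]), end = as.integer(df$end[keep]),
      sequence = toupper(as.character(df$sequence[keep])),
      condition = as.character(df$state[keep]),
      exposure = df$exposure[keep],
      m0 = as.numeric(m0[key[keep]]),
      mt = df$center[keep],
      mmaxD = as.numeric(maxd[key[keep]]),
      replicate = stats::ave(seq_along(which(keep)),
                             key[keep], df$state[keep], df$exposure[keep],
                             FUN = seq_along),
      stringsAsFactors = FALSE)
  }
  tab <- StateTable(records = rec, proteins = proteins)
  methods::validObject(tab)
  tab
}

#' Write a peptide-level HDX state table
#'
#' Writes the native-dialect CSV that [readPeptideStateTable()] reads back;
#' the round trip preserves centroid masses to full double precision.
#'
#' @param table a [StateTable-class]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writePeptideStateTable <- function(table, path) {
  stopifnot(methods::is(table, "StateTable"))
  methods::validObject(table)
  utils::write.csv(format(records(table), digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Reads a FASTA file into a list of [ProteinEntry-class] (sequence only).
#' Sequences are uppercased and trailing `*` stop characters stripped;
#' non-amino-acid characters are rejected.
#'
#' @param path FASTA file path
#' @return list of [ProteinEntry-class]
#' @export
readProteinFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) stopUsage("no FASTA records in ", path)
  lapply(seq_along(seqs), function(i) {
    s <- toupper(gsub("\\*$", "", as.character(seqs[[i]])))
    ProteinEntry(name = names(seqs)[i], sequence = s)
  })
}

#' Read a master sequence alignment
#'
#' Reads an alignment as gapped FASTA (or a two-column CSV `name,row`) into
#' [ProteinEntry-class] objects with `alignmentRow` set, from which
#' bidirectional sequential/alignment coordinate maps can be built with
#' [buildAlignmentMap()]. All rows must have equal length.
#'
#' @param path aligned FASTA or CSV file path
#' @param format `"fasta"` or `"csv"`; guessed from the extension by default
#' @param domainBoundary optional alignment column closing the first
#'   (variable) domain, attached to every entry
#' @return list of [ProteinEntry-class] with alignment rows
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "csv"),
                          domainBoundary = NA_real_) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "fasta"
  if (format == "fasta") {
    aln <- Biostrings::readAAStringSet(path)
    rows <- stats::setNames(toupper(as.character(aln)), names(aln))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("name", "row") %in% tolower(names(df))))
      stopUsage("alignment CSV needs columns 'name' and 'row'")
    names(df) <- tolower(names(df))
    rows <- stats::setNames(toupper(df$row), df$name)
  }
  if (!length(rows)) stopUsage("no alignment rows in ", path)
  if (length(unique(nchar(rows))) != 1L)
    stopUsage("alignment rows have unequal lengths")
  lapply(names(rows), function(nm)
    ProteinEntry(name = nm,
                 sequence = gsub("-", "", rows[[nm]], fixed = TRUE),
                 alignmentRow = rows[[nm]],
                 domainBoundary = domainBoundary))
}

#' Write a residue-level deuteration table
#'
#' Emits a [ResidueExchangeMap-class] as long-format CSV with columns
#' `protein, alignment_position, condition, exposure_s, percentD, covered`.
#' Uncovered cells are written with `covered=false` and an empty percentD
#' field.
#'
#' @param map a [ResidueExchangeMap-class]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeResidueTable <- function(map, path) {
  stopifnot(methods::is(map, "ResidueExchangeMap"))
  grid <- expand.grid(i = seq_along(map@positions),
                      j = seq_along(map@conditions),
                      k = seq_along(map@times))
  df <- data.frame(
    protein = map@protein,
    alignment_position = map@positions[grid$i],
    condition = map@conditions[grid$j],
    exposure_s = map@times[grid$k],
    percentD = map@percentD[cbind(grid$i, grid$j, grid$k)],
    covered = ifelse(map@coverage[cbind(grid$i, grid$j, grid$k)],
                     "true", "false"))
  df <- df[order(df$alignment_position, df$condition, df$exposure_s), ]
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a residue-level deuteration table
#'
#' Reads the long-format CSV written by [writeResidueTable()] back into a
#' [ResidueExchangeMap-class].
#'
#' @param path CSV path
#' @return a [ResidueExchangeMap-class]
#' @export
readResidueTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("protein", "alignment_position", "condition", "exposure_s",
           "percentD", "covered")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stopUsage("residue table is missing column(s): ",
              paste(missing, collapse = ", "))
  pos <- sort(unique(df$alignment_position))
  cond <- unique(df$condition)
  times <- sort(unique(df$exposure_s))
  arr <- array(NA_real_, c(length(pos), length(cond), length(times)))
  cov <- array(FALSE, dim(arr))
  idx <- cbind(match(df$alignment_position, pos),
               match(df$condition, cond),
               match(df$exposure_s, times))
  arr[idx] <- suppressWarnings(as.numeric(df$percentD))
  cov[idx] <- df$covered %in% c("true", "TRUE", TRUE)
  arr[!cov] <- NA_real_
  ResidueExchangeMap(protein = df$protein[1], positions = as.integer(pos),
                     conditions = cond, times = as.numeric(times),
                     percentD = arr, coverage = cov)
}

.REPORT_SCHEMA <- "hdxlc-report/1"

reportPayload <- function(object) {
  if (methods::is(object, "BindingFit")) {
    list(type = "BindingFit", model = object@model,
         D0 = object@d0, deltaDmax = object@deltaDmax, EC50 = object@ec50,
         deltaAtMax = object@deltaAtMax, maxConc = object@maxConc,
         se = as.list(object@se), residual = object@residual,
         unidentifiable = object@unidentifiable,
         converged = object@converged)
  } else if (methods::is(object, "ProteolysisTimecourse")) {
    list(type = "ProteolysisTimecourse", protein = object@protein,
         condition = object@condition,
         time_h = object@points$time, fraction = object@points$fraction,
         fit = object@fit, auc = object@auc)
  } else if (methods::is(object, "StabilityComparison")) {
    list(type = "StabilityComparison", xlab = object@xlab,
         ylab = object@ylab, r = object@r, p = object@p,
         protein = object@metrics$protein,
         x = object@metrics$x, y = object@metrics$y)
  } else if (is.list(object) && !is.data.frame(object)) {
    lapply(object, reportPayload)
  } else {
    stopUsage("writeReport does not know how to serialise objects of class ",
              paste(class(object), collapse = "/"))
  }
}

#' @describeIn writeReport serialise any supported product (or a plain list
#'   of them) with schema version, parameters and seed metadata
#' @param parameters optional named list recorded under `parameters`
#' @param seed optional integer recorded under `seed`
#' @export
setMethod("writeReport", "ANY", function(object, path, parameters = list(),
                                         seed = NA_integer_) {
  payload <- list(schema = .REPORT_SCHEMA,
                  parameters = parameters,
                  seed = seed,
                  results = reportPayload(object))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
})

#' Read a simulation configuration file
#'
#' Reads a YAML configuration describing a synthetic experiment. Recognised
#' keys (all optional, with the experiment's defaults): `labeling_times_s`
#' (default the 10 s - 16 h grid), `label_fraction` (0.9),
#' `noise_sd_da` (0.20), `back_exchange_retention` (0.85),
#' `deuteron_mass_da` (1.00628), `seed` (1). Unknown keys are rejected so
#' that typos do not silently fall back to defaults.
#'
#' @param path YAML file path
#' @return named list of configuration values
#' @export
readSimulationConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(labeling_times_s = hdxLabelingTimes(),
                   label_fraction = 0.9, noise_sd_da = 0.20,
                   back_exchange_retention = 0.85,
                   deuteron_mass_da = DEUTERON_MASS, seed = 1L)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stopUsage("unknown configuration key(s): ",
              paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, cfg)
  if (out$label_fraction <= 0 || out$label_fraction > 1)
    stopUsage("label_fraction must be in (0, 1]")
  if (out$noise_sd_da < 0) stopUsage("noise_sd_da must be >= 0")
  out
}
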