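#' Accessor generics
#'
#' Small accessor generics for the S4 containers in this package:
#' `records()` returns the peptide-level observation table of a
#' [StateTable-class]; `proteinEntries()` its protein annotations;
#' `deuteration()` the percent-deuteration (or difference) array of a
#' residue-level map; `coverage()` its logical coverage mask;
#' `titrationPoints()` the (concentration, replicate, uptake) table of a
#' [TitrationSeries-class]; `timecoursePoints()` the (time, fraction intact)
#' table of a [ProteolysisTimecourse-class].
#'
#' @param object an object of the documented class
#' @return the component named above; see the class documentation for details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("proteinEntries", function(object) standardGeneric("proteinEntries"))

#' @rdname accessors
#' @export
setGeneric("deuteration", function(object) standardGeneric("deuteration"))

#' @rdname accessors
#' @export
setGeneric("coverage", function(object) standardGeneric("coverage"))

#' @rdname accessors
#' @export
setGeneric("titrationPoints", function(object) standardGeneric("titrationPoints"))

#' @rdname accessors
#' @export
setGeneric("timecoursePoints", function(object) standardGeneric("timecoursePoints"))

#' Write a machine-readable JSON report
#'
#' Serialises an analysis product to JSON with a schema version and
#' deterministic key order, so that identical inputs give byte-identical
#' files. Supported products: [BindingFit-class],
#' [ProteolysisTimecourse-class], [StabilityComparison-class], and plain
#' lists of these.
#'
#' @param object the analysis product
#' @param path output file path
#' @param ... further arguments passed to methods
#' @return `path`, invisibly.
#' @export
setGeneric("writeReport", function(object, path, ...) standardGeneric("writeReport"))
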