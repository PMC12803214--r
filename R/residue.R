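# Sequential indices of exchange-reporting residues for a peptide on a real
# sequence: the first two peptide residues and prolines never report, nor
# does the protein's N-terminal residue.
reportersFromSequence <- function(sequence, start, end) {
  idx <- (start + 2L):end
  res <- strsplit(substr(sequence, start + 2L, end), "")[[1]]
  idx[res != "P" & idx != 1L]
}

#' Bidirectional sequential/alignment coordinate map
#'
#' From a protein's gapped row in the master alignment, builds the two
#' lookup vectors between its 1-based sequential numbering and the 1-based
#' alignment numbering. Gap columns map to `NA` (no residue of this protein
#' occupies them).
#'
#' @param entry a [ProteinEntry-class] with `alignmentRow` set (a gapless
#'   entry yields the identity map)
#' @return list with `seqToAln` (length = sequence length) and `alnToSeq`
#'   (length = alignment length, `NA` at gaps)
#' @export
buildAlignmentMap <- function(entry) {
  stopifnot(methods::is(entry, "ProteinEntry"))
  row <- if (nzchar(entry@alignmentRow)) entry@alignmentRow else entry@sequence
  if (gsub("-", "", row, fixed = TRUE) != entry@sequence)
    stopUsage("alignment row is inconsistent with the sequence")
  chars <- strsplit(row, "")[[1]]
  occupied <- chars != "-"
  alnToSeq <- rep(NA_integer_, length(chars))
  alnToSeq[occupied] <- seq_len(sum(occupied))
  list(seqToAln = which(occupied), alnToSeq = alnToSeq)
}

#' Map an interval between sequential and alignment coordinates
#'
#' Inclusive interval mapping through a [buildAlignmentMap()] lookup.
#' Sequential to alignment may lengthen the interval across interior gap
#' columns (not an error); alignment to sequential drops gap columns, and
#' an interval lying entirely in a gap region is absent (`integer(0)`).
#'
#' @param map a coordinate map from [buildAlignmentMap()]
#' @param start,end 1-based inclusive interval bounds
#' @param direction `"sequential_to_alignment"` or
#'   `"alignment_to_sequential"`
#' @return integer `c(start, end)` in the target coordinates, or
#'   `integer(0)` when absent
#' @examples
#' m <- list(seqToAln = c(1L, 2L, 4L), alnToSeq = c(1L, 2L, NA, 3L))
#' mapInterval(m, 2, 3, "sequential_to_alignment")  # 2 4
#' @export
mapInterval <- function(map, start, end,
                        direction = c("sequential_to_alignment",
                                      "alignment_to_sequential")) {
  direction <- match.arg(direction)
  if (start > end) stopUsage("start must not exceed end")
  if (direction == "sequential_to_alignment") {
    if (start < 1 || end > length(map$seqToAln))
      stopUsage("sequential interval out of range")
    c(map$seqToAln[start], map$seqToAln[end])
  } else {
    if (start < 1 || end > length(map$alnToSeq))
      stopUsage("alignment interval out of range")
    hits <- map$alnToSeq[start:end]
    hits <- hits[!is.na(hits)]
    if (!length(hits)) integer(0) else range(hits)
  }
}

# Bounded least squares min ||A x - b||^2, lo <= x <= hi, via L-BFGS-B from
# a feasible start.
.boundedLS <- function(A, b, lo = 0, hi = 100, start = NULL) {
  if (is.null(start)) start <- rep((lo + hi) / 2, ncol(A))
  start <- pmin(pmax(start, lo), hi)
  fn <- function(x) { r <- A %*% x - b; sum(r * r) }
  gr <- function(x) as.numeric(2 * crossprod(A, A %*% x - b))
  stats::optim(start, fn, gr, method = "L-BFGS-B",
               lower = lo, upper = hi,
               control = list(maxit = 2000L, factr = 1e2))$par
}

#' Reduce peptide-level deuteration to single residues
#'
#' Projects back-exchange-corrected peptide percent deuteration onto
#' single-residue master-alignment coordinates. Replicates are averaged
#' first; records flagged `missing` or `out_of_range` are excluded. Two
#' reduction schemes:
#'
#' * `weighted_average` (default): each residue's value is the mean of the
#'   %D of the peptides in which it is an exchangeable reporter, weighted
#'   by `1 / N_exch` of each peptide — short peptides, which localise
#'   better, count more.
#' * `nnls`: solves the linear system (peptide uptake in %D-residue units =
#'   sum of its reporters' residue values) as a bounded least-squares
#'   problem with residue values constrained to `[0, 100]`.
#'
#' Residues reported by no peptide are uncovered. Both protomers of a
#' homodimer are assumed equivalent: one residue map per protein.
#'
#' @param table a [StateTable-class] (proteins with alignment rows attached
#'   place residues on alignment coordinates; otherwise sequential
#'   coordinates are used)
#' @param method `"weighted_average"` or `"nnls"`
#' @param tolerance out-of-range tolerance passed to [computePercentD()]
#' @return a [ResidueExchangeMap-class] for a single-protein table, else a
#'   named list of maps
#' @export
reduceToResidues <- function(table, method = c("weighted_average", "nnls"),
                             tolerance = 5) {
  method <- match.arg(method)
  ut <- uptakeTable(table, tolerance)
  ut <- ut[ut$flag == "ok" & !is.na(ut$percentD), , drop = FALSE]
  if (!nrow(ut)) stopUsage("no usable (ok-flagged) percent-D values")
  prots <- proteinEntries(table)
  protNames <- vapply(prots, function(p) p@name, character(1))
  out <- lapply(unique(ut$protein), function(pn) {
    sub <- ut[ut$protein == pn, , drop = FALSE]
    entry <- if (pn %in% protNames) prots[[match(pn, protNames)]] else NULL
    .reduceOne(sub, entry, method)
  })
  names(out) <- unique(ut$protein)
  if (length(out) == 1L) out[[1L]] else out
}

.reduceOne <- function(ut, entry, method) {
  seqstr <- if (!is.null(entry)) entry@sequence else
    NULL
  # replicate means per peptide x condition x time
  agg <- aggregateReplicates(ut, by = c("protein", "start", "end", "sequence",
                                        "condition", "exposure"),
                             valueColumn = "percentD")
  conds <- unique(agg$condition)
  times <- sort(unique(agg$exposure))
  coordMap <- if (!is.null(entry)) buildAlignmentMap(entry) else NULL
  nAln <- if (!is.null(coordMap)) length(coordMap$alnToSeq) else
    max(agg$end)
  positions <- seq_len(nAln)
  arr <- array(NA_real_, c(nAln, length(conds), length(times)),
               dimnames = list(NULL, conds, as.character(times)))
  cov <- array(FALSE, dim(arr), dimnames = dimnames(arr))
  for (j in seq_along(conds)) for (k in seq_along(times)) {
    cell <- agg[agg$condition == conds[j] & agg$exposure == times[k], ,
                drop = FALSE]
    if (!nrow(cell)) next
    reps <- lapply(seq_len(nrow(cell)), function(p) {
      if (!is.null(seqstr))
        reportersFromSequence(seqstr, cell$start[p], cell$end[p])
      else setdiff((cell$start[p] + 2L):cell$end[p], 1L)
    })
    residues <- sort(unique(unlist(reps)))
    x <- if (method == "weighted_average" || nrow(cell) == 1L) {
      .weightedAverage(cell, reps, residues, clip = FALSE)
    } else {
      A <- matrix(0, nrow(cell), length(residues))
      for (p in seq_len(nrow(cell)))
        A[p, match(reps[[p]], residues)] <- 1
      b <- vapply(seq_len(nrow(cell)),
                  function(p) cell$mean[p] * length(reps[[p]]), numeric(1))
      # start from the weighted average for fast, stable convergence
      wstart <- .weightedAverage(cell, reps, residues, clip = TRUE)
      stats::setNames(.boundedLS(A, b, 0, 100, start = wstart), residues)
    }
    seqIdx <- as.integer(names(x))
    alnIdx <- if (!is.null(coordMap)) coordMap$seqToAln[seqIdx] else seqIdx
    arr[alnIdx, j, k] <- pmin(pmax(x, 0), 100)
    cov[alnIdx, j, k] <- TRUE
  }
  ResidueExchangeMap(protein = ut$protein[1], positions = positions,
                     conditions = conds, times = as.numeric(times),
                     percentD = arr, coverage = cov)
}

# 1/N_exch-weighted mean of peptide %D per reporter residue
.weightedAverage <- function(cell, reps, residues, clip = FALSE) {
  num <- den <- stats::setNames(numeric(length(residues)), residues)
  for (p in seq_len(nrow(cell))) {
    w <- 1 / length(reps[[p]])
    key <- as.character(reps[[p]])
    num[key] <- num[key] + w * cell$mean[p]
    den[key] <- den[key] + w
  }
  x <- num / den
  if (clip) pmin(pmax(x, 0), 100) else x
}

#' Condition-versus-condition residue difference map
#'
#' Cellwise `%D(condA) - %D(condB)` over a residue map, defined only where
#' both conditions are covered. Stabilizer-induced protection appears as
#' negative values.
#'
#' @param map a [ResidueExchangeMap-class]
#' @param condA,condB condition labels present in the map
#' @return a [DifferenceMap-class]
#' @export
differenceMap <- function(map, condA, condB) {
  stopifnot(methods::is(map, "ResidueExchangeMap"))
  if (!condA %in% map@conditions || !condB %in% map@conditions)
    stopUsage("unknown condition label; map has: ",
              paste(map@conditions, collapse = ", "))
  ja <- match(condA, map@conditions); jb <- match(condB, map@conditions)
  delta <- map@percentD[, ja, , drop = TRUE] -
    map@percentD[, jb, , drop = TRUE]
  delta <- matrix(delta, length(map@positions), length(map@times))
  both <- matrix(map@coverage[, ja, ] & map@coverage[, jb, ],
                 length(map@positions), length(map@times))
  delta[!both] <- NA_real_
  DifferenceMap(protein = map@protein, positions = map@positions,
                times = map@times, deltaPercentD = delta,
                conditionPair = c(condA, condB))
}

#' Area under the exchange curve
#'
#' Scalar stability summary of one condition: per residue, the trapezoidal
#' integral of %D over log10(time in seconds) — the labeling grid is
#' log-spaced, so a linear time axis would be dominated by the longest
#' timepoint — summed over the residues covered at every time in every
#' compared condition. The common-coverage residue set is computed once per
#' comparison group and returned alongside the area so that compared AUCs
#' always integrate the same residues.
#'
#' @param map a [ResidueExchangeMap-class] with at least 2 timepoints
#' @param condition the condition to integrate
#' @param comparedConditions conditions defining the common-coverage
#'   residue set (default: all conditions in the map)
#' @param timeAxis `"log10"` (default) or `"linear"`
#' @return list with `auc` (scalar), `perResidue` (named numeric) and
#'   `residues` (the common-coverage set, alignment coordinates)
#' @export
exchangeAUC <- function(map, condition,
                        comparedConditions = map@conditions,
                        timeAxis = c("log10", "linear")) {
  timeAxis <- match.arg(timeAxis)
  stopifnot(methods::is(map, "ResidueExchangeMap"))
  if (!condition %in% map@conditions)
    stopUsage("unknown condition label: ", condition)
  if (length(map@times) < 2L)
    stopUsage("exchange AUC needs at least 2 timepoints")
  times <- map@times
  if (timeAxis == "log10") {
    if (any(times <= 0))
      stopUsage("log10 time axis requires strictly positive times")
    x <- log10(times)
  } else x <- times
  js <- match(comparedConditions, map@conditions)
  if (anyNA(js)) stopUsage("comparedConditions not all present in the map")
  common <- apply(map@coverage[, js, , drop = FALSE], 1L, all)
  j <- match(condition, map@conditions)
  per <- vapply(which(common), function(i)
    pracma::trapz(x, map@percentD[i, j, ]), numeric(1))
  names(per) <- map@positions[common]
  list(auc = sum(per), perResidue = per,
       residues = map@positions[common])
}
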