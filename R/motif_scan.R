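# Eight-cysteine-motif (8CM) scanning.
#
# The nsLTP scaffold is C-Xn-C-Xn-CC-Xn-CXC-Xn-C-Xn-C: eight cysteines with
# two anchors (the adjacent CC pair C3C4 and the CXC triplet C5-X-C6) and
# five variable inter-cysteine gaps g1 (C1->C2), g2 (C2->C3), g3 (C4->C5),
# g4 (C6->C7) and g5 (C7->C8).

#' Gap bounds for the 8CM scanner
#'
#' Inclusive (min, max) bounds for the five variable gaps. The defaults are
#' the union of the printed wheat spacing ranges per gap, widened by a small
#' margin, and are fully user-configurable.
#'
#' @param g1,g2,g3,g4,g5 length-2 integer vectors `c(min, max)`; all mins
#'   must be at least 1.
#' @return an object of class `gap_bounds`.
#' @export
gap_bounds <- function(g1 = c(3L, 21L), g2 = c(8L, 29L), g3 = c(8L, 23L),
                       g4 = c(8L, 38L), g5 = c(3L, 22L)) {
  b <- list(g1 = as.integer(g1), g2 = as.integer(g2), g3 = as.integer(g3),
            g4 = as.integer(g4), g5 = as.integer(g5))
  for (nm in names(b)) {
    if (length(b[[nm]]) != 2L || b[[nm]][1] < 1L || b[[nm]][1] > b[[nm]][2])
      stop(sprintf("invalid bounds for %s: need 1 <= min <= max", nm))
  }
  structure(b, class = "gap_bounds")
}

in_bounds <- function(x, b) x >= b[1] & x <= b[2]

#' Scan a protein for the eight-cysteine motif
#'
#' Enumerates every increasing 8-tuple of cysteine positions satisfying the
#' CC / CXC anchors and the gap bounds. By default, overlapping candidates
#' are resolved greedily by leftmost start then smallest total span;
#' `all_candidates = TRUE` returns the full enumeration.
#'
#' @param protein protein string or `seq_record`.
#' @param bounds a [gap_bounds()] object.
#' @param all_candidates return every candidate instead of the resolved,
#'   non-overlapping set.
#' @param id sequence id recorded in the result (defaults to the
#'   `seq_record` id or `"seq"`).
#' @param frame optional translation frame label carried through to the
#'   result (used by the six-frame DNA mode).
#' @return data frame with one row per match: `sequence_id`, `frame`,
#'   `c1`..`c8` (0-based cysteine indices), `g1`..`g5`, `cxc_x` (the single
#'   residue between C5 and C6) and `span`; zero rows when nothing matches.
#' @export
scan_eight_cm <- function(protein, bounds = gap_bounds(),
                          all_candidates = FALSE, id = NULL, frame = NA) {
  if (is.null(id))
    id <- if (inherits(protein, "seq_record")) protein$id else "seq"
  s <- as_residues(protein, "protein")
  chars <- seq_chars(s)
  cys <- which(chars == "C") - 1L  # 0-based
  empty <- data.frame(sequence_id = character(0), frame = character(0),
                      c1 = integer(0), c2 = integer(0), c3 = integer(0),
                      c4 = integer(0), c5 = integer(0), c6 = integer(0),
                      c7 = integer(0), c8 = integer(0),
                      g1 = integer(0), g2 = integer(0), g3 = integer(0),
                      g4 = integer(0), g5 = integer(0),
                      cxc_x = character(0), span = integer(0),
                      stringsAsFactors = FALSE)
  if (length(cys) < 8L) return(empty)

  cset <- cys
  cc3 <- cys[(cys + 1L) %in% cset]   # candidate C3 (C4 = C3 + 1)
  cxc5 <- cys[(cys + 2L) %in% cset]  # candidate C5 (C6 = C5 + 2)
  rows <- list()
  for (p3 in cc3) {
    p4 <- p3 + 1L
    p2s <- cys[cys < p3 & in_bounds(p3 - cys - 1L, bounds$g2)]
    if (length(p2s) == 0L) next
    for (p5 in cxc5[cxc5 > p4 & in_bounds(cxc5 - p4 - 1L, bounds$g3)]) {
      p6 <- p5 + 2L
      p7s <- cys[cys > p6 & in_bounds(cys - p6 - 1L, bounds$g4)]
      if (length(p7s) == 0L) next
      for (p2 in p2s) {
        p1s <- cys[cys < p2 & in_bounds(p2 - cys - 1L, bounds$g1)]
        for (p1 in p1s) for (p7 in p7s) {
          p8s <- cys[cys > p7 & in_bounds(cys - p7 - 1L, bounds$g5)]
          for (p8 in p8s) {
            rows[[length(rows) + 1L]] <-
              c(p1, p2, p3, p4, p5, p6, p7, p8)
          }
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  m <- do.call(rbind, rows)
  res <- data.frame(sequence_id = id, frame = as.character(frame),
                    c1 = m[, 1], c2 = m[, 2], c3 = m[, 3], c4 = m[, 4],
                    c5 = m[, 5], c6 = m[, 6], c7 = m[, 7], c8 = m[, 8],
                    stringsAsFactors = FALSE)
  res$g1 <- res$c2 - res$c1 - 1L
  res$g2 <- res$c3 - res$c2 - 1L
  res$g3 <- res$c5 - res$c4 - 1L
  res$g4 <- res$c7 - res$c6 - 1L
  res$g5 <- res$c8 - res$c7 - 1L
  res$cxc_x <- chars[res$c5 + 2L]
  res$span <- res$c8 - res$c1 + 1L
  res <- res[order(res$c1, res$span, res$c2, res$c3, res$c5, res$c7,
                   res$c8), , drop = FALSE]
  rownames(res) <- NULL
  if (all_candidates) return(res)
  # leftmost-start, then smallest-span greedy resolution of overlaps
  chosen <- logical(nrow(res))
  occupied_end <- -1L
  for (i in seq_len(nrow(res))) {
    if (res$c1[i] > occupied_end) {
      chosen[i] <- TRUE
      occupied_end <- res$c8[i]
    }
  }
  out <- res[chosen, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of proteins for the 8CM
#'
#' @param proteins named character vector of protein sequences.
#' @inheritParams scan_eight_cm
#' @return row-bound data frame of matches (see [scan_eight_cm()]).
#' @export
scan_eight_cm_set <- function(proteins, bounds = gap_bounds(),
                              all_candidates = FALSE) {
  stopifnot(!is.null(names(proteins)))
  out <- lapply(names(proteins), function(nm) {
    scan_eight_cm(proteins[[nm]], bounds, all_candidates, id = nm)
  })
  do.call(rbind, out)
}

#' Scan DNA for the 8CM in all six frames
#'
#' Translates the sequence in six frames and scans each translation;
#' matches carry their frame label. This is the desk-scale stand-in for a
#' translated homology search over candidate windows.
#'
#' @param dna DNA string or `seq_record`.
#' @inheritParams scan_eight_cm
#' @return data frame of matches with the `frame` column set.
#' @export
scan_dna_six_frame <- function(dna, bounds = gap_bounds(),
                               all_candidates = FALSE, id = NULL) {
  if (is.null(id))
    id <- if (inherits(dna, "seq_record")) dna$id else "seq"
  tr <- six_frame_translate(dna)
  out <- lapply(names(tr), function(fr) {
    if (nchar(tr[[fr]]) == 0L) return(NULL)
    scan_eight_cm(tr[[fr]], bounds, all_candidates, id = id, frame = fr)
  })
  do.call(rbind, out)
}

# "13-15,19" style rendering of a set of observed gap values
render_gap_values <- function(values) {
  v <- sort(unique(as.integer(values)))
  if (length(v) == 0L) return("")
  runs <- split(v, cumsum(c(1L, diff(v) != 1L)))
  paste(vapply(runs, function(r) {
    if (length(r) == 1L) as.character(r)
    else paste0(r[1], "-", r[length(r)])
  }, character(1)), collapse = ",")
}

#' Per-type spacing signatures
#'
#' Summarises the observed inter-cysteine gap values of matched 8CMs per
#' type, in the conventional `CXn...` notation, and flags gap values unique
#' to a single type.
#'
#' @param matches data frame of 8CM matches with columns `g1`..`g5` and a
#'   `type` column.
#' @return list with one element per type: `n`, `gaps` (list of observed
#'   value multisets g1..g5), `pattern` (rendered signature string) and
#'   `unique_values` (per gap, values seen in this type only).
#' @export
spacing_signature <- function(matches) {
  stopifnot("type" %in% names(matches))
  gaps <- paste0("g", 1:5)
  types <- sort(unique(matches$type))
  per_type_values <- lapply(types, function(tp) {
    lapply(matches[matches$type == tp, gaps, drop = FALSE], as.integer)
  })
  names(per_type_values) <- types
  out <- lapply(types, function(tp) {
    vals <- per_type_values[[tp]]
    rendered <- vapply(vals, render_gap_values, character(1))
    uniq <- lapply(gaps, function(g) {
      mine <- unique(vals[[g]])
      others <- unique(unlist(lapply(setdiff(types, tp), function(o) {
        per_type_values[[o]][[g]]
      })))
      sort(setdiff(mine, others))
    })
    names(uniq) <- gaps
    list(type = tp, n = sum(matches$type == tp), gaps = vals,
         pattern = paste0("CX", rendered["g1"], "CX", rendered["g2"],
                          "CCX", rendered["g3"], "CXCX", rendered["g4"],
                          "CX", rendered["g5"], "C"),
         unique_values = uniq)
  })
  names(out) <- types
  out
}

#' CXC polarity per type
#'
#' Fraction of matches whose X residue (between C5 and C6) is hydrophobic
#' (set A,V,L,I,M,F,W,C,P,G); residues outside the set count hydrophilic,
#' unknown residues (X) are excluded from the denominator with a warning.
#'
#' @param matches data frame of 8CM matches with `cxc_x` and `type` columns.
#' @return data frame: type, n, n_hydrophobic, fraction_hydrophobic.
#' @export
cxc_polarity <- function(matches) {
  stopifnot(all(c("cxc_x", "type") %in% names(matches)))
  unknown <- matches$cxc_x == "X"
  if (any(unknown)) {
    warning(sprintf("excluding %d match(es) with unknown CXC X residue",
                    sum(unknown)))
    matches <- matches[!unknown, , drop = FALSE]
  }
  types <- sort(unique(matches$type))
  out <- lapply(types, function(tp) {
    x <- matches$cxc_x[matches$type == tp]
    data.frame(type = tp, n = length(x),
               n_hydrophobic = sum(x %in% HYDROPHOBIC_SET),
               fraction_hydrophobic = mean(x %in% HYDROPHOBIC_SET),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out) %||%
    data.frame(type = character(0), n = integer(0),
               n_hydrophobic = integer(0),
               fraction_hydrophobic = numeric(0))
}

#' Position-count matrices of matched 8CMs
#'
#' Builds, per type, a residue x column count matrix over the aligned 8CM:
#' the eight cysteine columns, the fixed CXC X column, and per-gap columns
#' left-aligned and padded to the maximum observed gap within the type.
#' Column sums equal the number of sequences whose gap covers the column.
#' The matrices are plain counts, consumable by any logo renderer.
#'
#' @param matches data frame of 8CM matches (with `type` column).
#' @param proteins named character vector of the matched protein sequences.
#' @return named list (per type) of 20 x n_columns integer matrices.
#' @export
position_counts <- function(matches, proteins) {
  stopifnot("type" %in% names(matches))
  types <- sort(unique(matches$type))
  out <- lapply(types, function(tp) {
    mm <- matches[matches$type == tp, , drop = FALSE]
    gmax <- vapply(paste0("g", 1:5), function(g) max(mm[[g]]), integer(1))
    labels <- c("C1", paste0("g1.", seq_len(gmax[1])),
                "C2", paste0("g2.", seq_len(gmax[2])),
                "C3", "C4", paste0("g3.", seq_len(gmax[3])),
                "C5", "X",
                "C6", paste0("g4.", seq_len(gmax[4])),
                "C7", paste0("g5.", seq_len(gmax[5])), "C8")
    counts <- matrix(0L, nrow = length(AA20), ncol = length(labels),
                     dimnames = list(AA20, labels))
    add <- function(col, residue) {
      if (residue %in% AA20)
        counts[residue, col] <<- counts[residue, col] + 1L
    }
    for (i in seq_len(nrow(mm))) {
      chars <- seq_chars(proteins[[mm$sequence_id[i]]])
      at <- function(pos0) chars[pos0 + 1L]
      add("C1", at(mm$c1[i])); add("C2", at(mm$c2[i]))
      add("C3", at(mm$c3[i])); add("C4", at(mm$c4[i]))
      add("C5", at(mm$c5[i])); add("X", at(mm$c5[i] + 1L))
      add("C6", at(mm$c6[i])); add("C7", at(mm$c7[i]))
      add("C8", at(mm$c8[i]))
      gap_starts <- c(g1 = mm$c1[i], g2 = mm$c2[i], g3 = mm$c4[i],
                      g4 = mm$c6[i], g5 = mm$c7[i])
      gap_lens <- c(mm$g1[i], mm$g2[i], mm$g3[i], mm$g4[i], mm$g5[i])
      for (g in 1:5) for (j in seq_len(gap_lens[g]))
        add(paste0("g", g, ".", j), at(gap_starts[g] + j))
    }
    counts
  })
  names(out) <- types
  out
}
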