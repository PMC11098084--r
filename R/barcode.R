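#' Button barcodes
#'
#' A barcode is the chromosome-specific pattern of adhesive "button" nodes
#' along one chain. Node indices are 0-based throughout the public API
#' (node 0 is the centromere), matching the convention used for gap arithmetic;
#' conversion to 1-based matrix rows happens internally.
#'
#' @param button_indices strictly increasing integer vector of 0-based node
#'   indices carrying buttons.
#' @param arm_length number of nodes on the arm.
#' @param min_gap smallest allowed gap between consecutive buttons; the
#'   constructors for uniform/random/gap-encoded codes enforce 2 (which keeps
#'   the cis rest separation above the capture radius), while editing
#'   operations such as [invert_barcode()] deliberately produce consecutive
#'   button tracts and pass 1.
#' @return an object of class `barcode`.
#' @export
#' @examples
#' barcode(c(0, 3, 6), arm_length = 48)
barcode <- function(button_indices, arm_length, min_gap = 1) {
  button_indices <- as.integer(button_indices)
  arm_length <- as.integer(arm_length)
  bc <- structure(list(buttons = button_indices, arm_length = arm_length),
                  class = "barcode")
  validate_barcode(bc, min_gap = min_gap)
  bc
}

#' Validate a barcode
#'
#' Checks that indices are strictly increasing, within `[0, arm_length)`, and
#' that consecutive gaps are at least `min_gap`.
#'
#' @param bc a `barcode`.
#' @param min_gap minimum consecutive gap to enforce (default 1).
#' @return `bc`, invisibly; errors on violation.
#' @export
validate_barcode <- function(bc, min_gap = 1) {
  stopifnot(inherits(bc, "barcode"))
  b <- bc$buttons
  if (length(b) < 1) stop("barcode must contain at least one button")
  if (anyNA(b)) stop("barcode indices must not be NA")
  if (any(b < 0L) || any(b >= bc$arm_length)) {
    stop("button indices must lie in [0, arm_length)")
  }
  if (length(b) > 1) {
    g <- diff(b)
    if (any(g <= 0)) stop("button indices must be strictly increasing")
    if (any(g < min_gap)) {
      stop(sprintf("gaps between buttons must be >= %d nodes", min_gap))
    }
  }
  invisible(bc)
}

#' @export
print.barcode <- function(x, ...) {
  cat(sprintf("<barcode> %d buttons on %d nodes: %s\n",
              length(x$buttons), x$arm_length,
              paste(x$buttons, collapse = ",")))
  invisible(x)
}

#' @export
format.barcode <- function(x, ...) {
  sprintf("%s / %d", paste(x$buttons, collapse = ","), x$arm_length)
}

#' Uniformly spaced barcode
#'
#' Buttons at `start, start + spacing, ...` up to `arm_length - 1`. Uniform
#' spacings of 3 vs 4 nodes on the two chromosomes are the reference
#' proof-of-concept layout.
#'
#' @param spacing gap between consecutive buttons, in nodes (>= 2).
#' @param arm_length nodes per arm.
#' @param start first button index (default 0, the centromere).
#' @return a `barcode`.
#' @export
#' @examples
#' uniform_barcode(3, 48)  # 16 buttons at 0,3,...,45
uniform_barcode <- function(spacing, arm_length, start = 0) {
  if (spacing < 2) stop("spacing must be >= 2 (capture-radius separation)")
  if (start < 0 || start >= arm_length) stop("start out of range")
  barcode(seq.int(start, arm_length - 1L, by = as.integer(spacing)),
          arm_length, min_gap = 2)
}

#' Random barcode
#'
#' Draws `n_buttons` distinct sorted node indices uniformly over all admissible
#' layouts inside `node_range` with all consecutive gaps at least `min_gap`.
#' Uniformity over admissible sets is obtained by the standard gap-removal
#' bijection: choosing sorted `x` with `diff(x) >= g` in `[lo, hi]` is
#' equivalent to choosing a plain sorted `n`-subset of `[lo, hi - (g-1)(n-1)]`.
#'
#' @param n_buttons number of buttons.
#' @param node_range integer vector `c(lo, hi)` of admissible 0-based indices
#'   (inclusive).
#' @param arm_length nodes per arm of the resulting barcode.
#' @param min_gap minimum gap between consecutive buttons (default 2).
#' @param fix_endpoints if `TRUE`, both `lo` and `hi` are forced to be buttons
#'   and only the interior buttons are drawn at random (used to compare random
#'   codes spanning the same endpoints as a reference code).
#' @return a `barcode`.
#' @export
#' @examples
#' set.seed(1)
#' random_barcode(5, c(0, 12), arm_length = 48)
random_barcode <- function(n_buttons, node_range, arm_length,
                           min_gap = 2, fix_endpoints = FALSE) {
  lo <- as.integer(node_range[1]); hi <- as.integer(node_range[2])
  n <- as.integer(n_buttons)
  if (hi < lo) stop("node_range must satisfy lo <= hi")
  if (n < 1) stop("n_buttons must be >= 1")
  g <- as.integer(min_gap)
  if (fix_endpoints) {
    if (n < 2) stop("fix_endpoints requires n_buttons >= 2")
    k <- n - 2L
    # interior indices in [lo + g, hi - g] with gaps >= g among themselves
    ilo <- lo + g; ihi <- hi - g
    if (k > 0L) {
      m <- ihi - ilo + 1L - (g - 1L) * (k - 1L)
      if (m < k) stop("infeasible random barcode constraints")
      y <- sort(sample.int(m, k)) - 1L
      interior <- ilo + y + (g - 1L) * (0:(k - 1L))
      idx <- c(lo, interior, hi)
    } else {
      if (hi - lo < g) stop("infeasible random barcode constraints")
      idx <- c(lo, hi)
    }
  } else {
    m <- hi - lo + 1L - (g - 1L) * (n - 1L)
    if (m < n) stop("infeasible random barcode constraints")
    y <- sort(sample.int(m, n)) - 1L
    idx <- lo + y + (g - 1L) * (0:(n - 1L))
  }
  barcode(idx, arm_length, min_gap = min(g, 2L))
}

# Industrial 2-of-5 symbology: each digit is five bars, exactly two wide.
# Standard bar-pattern table (W = wide, N = narrow).
code_2of5_table <- list(
  "0" = c("N", "N", "W", "W", "N"),
  "1" = c("W", "N", "N", "N", "W"),
  "2" = c("N", "W", "N", "N", "W"),
  "3" = c("W", "W", "N", "N", "N"),
  "4" = c("N", "N", "W", "N", "W"),
  "5" = c("W", "N", "W", "N", "N"),
  "6" = c("N", "W", "W", "N", "N"),
  "7" = c("N", "N", "N", "W", "W"),
  "8" = c("W", "N", "N", "W", "N"),
  "9" = c("N", "W", "N", "W", "N")
)

#' Encode a digit in code 2 of 5
#'
#' The industrial "code 2 of 5" symbology encodes each digit 0--9 as five bars
#' of which exactly two are wide; the spaces carry no information. On a
#' chromosome the bars become gaps between buttons: a wide bar is a gap of 6
#' nodes and a narrow bar a gap of 2 nodes, so every digit spans
#' `2*6 + 3*2 = 18` nodes and carries 6 buttons.
#'
#' @param digit integer in 0..9.
#' @param wide nodes per wide gap (default 6).
#' @param narrow nodes per narrow gap (default 2).
#' @return integer vector of 5 gaps.
#' @export
#' @examples
#' encode_2of5(0)  # c(2, 2, 6, 6, 2)
encode_2of5 <- function(digit, wide = 6, narrow = 2) {
  if (length(digit) != 1 || is.na(digit) || digit %% 1 != 0 ||
      digit < 0 || digit > 9) {
    stop("digit must be a single integer in 0..9")
  }
  bars <- code_2of5_table[[as.character(as.integer(digit))]]
  as.integer(ifelse(bars == "W", wide, narrow))
}

#' Barcode from a gap sequence
#'
#' Buttons at cumulative positions `start, start + g1, start + g1 + g2, ...`;
#' `k` gaps yield `k + 1` buttons.
#'
#' @param gaps integer vector of gaps (each >= 2).
#' @param arm_length nodes per arm.
#' @param start index of the first button (default 0).
#' @return a `barcode`.
#' @export
#' @examples
#' gaps_to_barcode(encode_2of5(0), arm_length = 48)  # buttons 0,2,4,10,16,18
gaps_to_barcode <- function(gaps, arm_length, start = 0) {
  gaps <- as.integer(gaps)
  if (any(gaps < 2)) stop("gaps must be >= 2 nodes")
  idx <- as.integer(start) + c(0L, cumsum(gaps))
  if (any(idx >= arm_length)) stop("gap sequence exceeds arm_length")
  barcode(idx, arm_length, min_gap = 2)
}

#' Gap sequence of a barcode
#'
#' Inverse of [gaps_to_barcode()]: returns `diff(button_indices)`.
#'
#' @param bc a `barcode`.
#' @return integer vector of gaps (length `n_buttons - 1`).
#' @export
barcode_to_gaps <- function(bc) {
  validate_barcode(bc)
  diff(bc$buttons)
}

#' Swap buttons and gaps within a barcode's span
#'
#' Over `span` (by default the stretch from the first to the last button),
#' every node that was a button becomes a non-button and vice versa, turning
#' the gaps into contiguous tracts of pairing sites. The result typically
#' contains consecutive buttons (gap 1), which is the point of the variant.
#' Inverting twice over the same explicit span restores the original code.
#'
#' @param bc a `barcode`.
#' @param span integer `c(lo, hi)` range (inclusive, 0-based) over which to
#'   complement; defaults to the range of the barcode's own buttons.
#' @return a `barcode` complementary to `bc` within the span.
#' @export
#' @examples
#' invert_barcode(barcode(c(0, 3), 48))  # buttons 1,2
invert_barcode <- function(bc, span = range(bc$buttons)) {
  validate_barcode(bc)
  if (span[1] < 0 || span[2] >= bc$arm_length) stop("span out of arm bounds")
  nodes <- seq.int(span[1], span[2])
  inv <- sort(union(setdiff(nodes, bc$buttons), setdiff(bc$buttons, nodes)))
  if (length(inv) == 0) stop("inversion of a fully buttoned span is empty")
  barcode(inv, bc$arm_length, min_gap = 1)
}

#' Shift a barcode along the arm
#'
#' All button indices are incremented by `offset` (which may be negative).
#' Used for the distal-shift and heterozygous/homozygous translocation
#' experiments.
#'
#' @param bc a `barcode`.
#' @param offset integer number of nodes to shift by.
#' @return a `barcode`.
#' @export
shift_barcode <- function(bc, offset) {
  validate_barcode(bc)
  idx <- bc$buttons + as.integer(offset)
  if (any(idx < 0L) || any(idx >= bc$arm_length)) {
    stop("shifted button indices out of range")
  }
  barcode(idx, bc$arm_length, min_gap = 1)
}

#' Reciprocal translocation between two barcodes
#'
#' Exchanges the button/non-button status of the nodes in `node_range_a` on
#' barcode A with the nodes in `node_range_b` on barcode B (equal-length,
#' inclusive 0-based ranges). Swapping each chromosome's full patch exchanges
#' the entire codes.
#'
#' @param bc_a,bc_b `barcode` objects.
#' @param node_range_a,node_range_b integer `c(lo, hi)` ranges of equal length.
#' @return list of two `barcode`s (`a`, `b`) after the swap.
#' @export
reciprocal_translocation <- function(bc_a, bc_b, node_range_a, node_range_b) {
  validate_barcode(bc_a); validate_barcode(bc_b)
  ra <- seq.int(node_range_a[1], node_range_a[2])
  rb <- seq.int(node_range_b[1], node_range_b[2])
  if (length(ra) != length(rb)) stop("translocated ranges must have equal length")
  if (min(ra) < 0 || max(ra) >= bc_a$arm_length ||
      min(rb) < 0 || max(rb) >= bc_b$arm_length) {
    stop("translocated range out of arm bounds")
  }
  in_a <- intersect(bc_a$buttons, ra)   # status of range A, as offsets
  in_b <- intersect(bc_b$buttons, rb)
  new_a <- sort(union(setdiff(bc_a$buttons, ra), ra[match(in_b, rb)]))
  new_b <- sort(union(setdiff(bc_b$buttons, rb), rb[match(in_a, ra)]))
  list(a = barcode(new_a, bc_a$arm_length, min_gap = 1),
       b = barcode(new_b, bc_b$arm_length, min_gap = 1))
}

#' Write barcodes to a text file
#'
#' One line per chromosome in the format
#' `chrom_id: i1,i2,...,ik / arm_length` with 0-based indices. The reader
#' [read_barcodes()] round-trips exactly.
#'
#' @param barcodes named list of `barcode` objects (names are chromosome ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_barcodes <- function(barcodes, path) {
  ids <- names(barcodes)
  if (is.null(ids) || any(ids == "")) {
    ids <- paste0("chr", seq_along(barcodes))
  }
  lines <- vapply(seq_along(barcodes), function(i) {
    sprintf("%s: %s", ids[i], format(barcodes[[i]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read barcodes from a text file
#'
#' @param path path to a file written by [write_barcodes()].
#' @return named list of `barcode` objects.
#' @export
read_barcodes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    colon <- regexpr(":", ln, fixed = TRUE)
    slash <- regexpr("/", ln, fixed = TRUE)
    if (colon < 0 || slash < colon) stop("malformed barcode line: ", ln)
    id <- trimws(substr(ln, 1, colon - 1))
    idx_str <- gsub("[[:space:]]", "", substr(ln, colon + 1, slash - 1))
    arm_str <- trimws(substr(ln, slash + 1, nchar(ln)))
    idx <- suppressWarnings(as.integer(strsplit(idx_str, ",", fixed = TRUE)[[1]]))
    arm <- suppressWarnings(as.integer(arm_str))
    if (anyNA(idx) || is.na(arm)) stop("malformed barcode line: ", ln)
    out[[id]] <- barcode(idx, arm, min_gap = 1)
  }
  out
}
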