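#' Piecewise liftover map between two mitochondrial reference assemblies
#'
#' A map between a source and a target mitochondrial coordinate system that
#' differ by a small set of deletions (bases present in the target, absent
#' from the source; stored in target coordinates) plus single-base
#' substitutions. The packaged default maps the 16,338 bp bovine reference
#' sequence (BRS, V00654) onto the 16,340 bp ARS-UCD1.2 mitochondrial contig:
#' two deletions (target positions 222 and 589) and twelve base differences.
#'
#' @param source_length length of the source reference in bp.
#' @param target_length length of the target reference in bp; must equal
#'   \code{source_length + length(deletions)}.
#' @param deletions strictly increasing target-coordinate positions absent
#'   from the source.
#' @param base_differences data.frame with columns \code{target_pos,
#'   target_base, source_pos, source_base} for substitution rows; carried for
#'   reference-consistency checks, they do not shift coordinates.
#' @return object of class \code{liftover_map}.
#' @export
liftover_map <- function(source_length, target_length,
                         deletions = integer(0),
                         base_differences = NULL) {
  deletions <- as.integer(deletions)
  if (target_length != source_length + length(deletions))
    stop("target_length must equal source_length + number of deletions")
  if (length(deletions) &&
      (is.unsorted(deletions, strictly = TRUE) ||
       any(deletions < 1 | deletions > target_length)))
    stop("deletions must be strictly increasing and within [1, target_length]")
  if (is.null(base_differences))
    base_differences <- data.frame(target_pos = integer(0),
                                   target_base = character(0),
                                   source_pos = integer(0),
                                   source_base = character(0),
                                   stringsAsFactors = FALSE)
  structure(list(source_length = as.integer(source_length),
                 target_length = as.integer(target_length),
                 deletions = deletions,
                 base_differences = base_differences),
            class = "liftover_map")
}

#' @export
print.liftover_map <- function(x, ...) {
  cat(sprintf("liftover_map: %d bp -> %d bp; %d deletion(s) at target %s; %d base difference(s)\n",
              x$source_length, x$target_length, length(x$deletions),
              paste(x$deletions, collapse = ", "),
              nrow(x$base_differences)))
  invisible(x)
}

#' Read a liftover map from a TSV file
#'
#' Columns: \code{type} (\code{deletion} or \code{substitution}),
#' \code{target_pos}, \code{target_base}, \code{source_pos},
#' \code{source_base} (\code{.} for deletion rows).
#'
#' @param path map file; defaults to the packaged BRS-to-ARS map.
#' @param source_length,target_length reference lengths (defaults are the
#'   BRS/ARS pair).
#' @return a \code{liftover_map}.
#' @export
read_liftover_map <- function(path = system.file("extdata",
                                                 "brs_to_ars_map.tsv",
                                                 package = "mitodiv"),
                              source_length = 16338L,
                              target_length = 16340L) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("type", "target_pos", "target_base", "source_pos", "source_base")
  if (!all(need %in% names(m)))
    stop("map file must have columns: ", paste(need, collapse = ", "))
  del <- sort(as.integer(m$target_pos[m$type == "deletion"]))
  sub <- m[m$type == "substitution", , drop = FALSE]
  bd <- data.frame(target_pos = as.integer(sub$target_pos),
                   target_base = sub$target_base,
                   source_pos = as.integer(sub$source_pos),
                   source_base = sub$source_base,
                   stringsAsFactors = FALSE)
  liftover_map(source_length, target_length, del, bd)
}

#' The packaged BRS (V00654) to ARS-UCD1.2_M liftover map
#'
#' @return a \code{liftover_map} (16,338 bp to 16,340 bp, deletions at target
#'   positions 222 and 589, 12 base differences).
#' @export
default_liftover_map <- function() read_liftover_map()

#' Lift source-coordinate positions to the target reference
#'
#' A source position maps to the unique target position \code{t} with
#' \code{t = p + (number of target deletions <= t)}. With the default map
#' this gives +0 up to source 221, +1 for 222..587 and +2 from 588 on
#' (so 363 -> 364, 2536 -> 2538, 16338 -> 16340).
#'
#' @param map a \code{liftover_map}.
#' @param source_pos integer vector of 1-based source positions.
#' @return integer vector of target positions.
#' @export
lift_position <- function(map, source_pos) {
  stopifnot(inherits(map, "liftover_map"))
  if (any(source_pos < 1 | source_pos > map$source_length))
    stop("source position out of range [1, ", map$source_length, "]")
  vapply(as.integer(source_pos), function(p) {
    t <- p
    repeat {
      t_new <- p + sum(map$deletions <= t)
      if (t_new == t) break
      t <- t_new
    }
    t
  }, integer(1))
}

#' Map target-coordinate positions back to the source reference
#'
#' Inverse of \code{\link{lift_position}}. Target positions that are
#' deletions (absent from the source) return \code{NA_integer_}.
#'
#' @param map a \code{liftover_map}.
#' @param target_pos integer vector of 1-based target positions.
#' @return integer vector of source positions, \code{NA} where deleted.
#' @export
lift_position_inverse <- function(map, target_pos) {
  stopifnot(inherits(map, "liftover_map"))
  if (any(target_pos < 1 | target_pos > map$target_length))
    stop("target position out of range [1, ", map$target_length, "]")
  vapply(as.integer(target_pos), function(t) {
    if (t %in% map$deletions) return(NA_integer_)
    t - sum(map$deletions < t)
  }, integer(1))
}

#' Lift a defining-variant set onto a new reference
#'
#' Lifts each variant's position and drops variants whose allele equals the
#' target reference base at the lifted position (no longer variant on the new
#' reference). Alleles are never altered.
#'
#' @param map a \code{liftover_map}.
#' @param variants data.frame with columns \code{haplogroup, pos, allele}
#'   (positions in source coordinates).
#' @param target_reference target reference sequence (character scalar or
#'   \code{Biostrings::DNAString}) of length \code{map$target_length}.
#' @return list with \code{lifted} and \code{dropped} data.frames (the
#'   dropped one gains a \code{reason} column); the two partition the input.
#' @export
lift_variant_set <- function(map, variants, target_reference) {
  stopifnot(inherits(map, "liftover_map"))
  target_reference <- as.character(target_reference)
  if (nchar(target_reference) != map$target_length)
    stop("target_reference length must equal map$target_length")
  ref <- strsplit(target_reference, "")[[1]]
  empty <- variants[0, , drop = FALSE]
  if (nrow(variants) == 0)
    return(list(lifted = empty,
                dropped = cbind(empty, reason = character(0))))
  out <- variants
  out$pos <- lift_position(map, variants$pos)
  same <- toupper(out$allele) == toupper(ref[out$pos])
  dropped <- out[same, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "matches_target_reference"
  lifted <- out[!same, , drop = FALSE]
  rownames(lifted) <- rownames(dropped) <- NULL
  list(lifted = lifted, dropped = dropped)
}
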