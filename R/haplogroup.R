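#' Haplogroup definition set
#'
#' A mapping from haplogroup names to their defining variants (position +
#' diagnostic allele, both relative to a stated reference), in the style of
#' the DomeTree cattle haplogroup catalogue. Name prefixes encode nesting
#' (e.g. T3 within T).
#'
#' @param groups named list; each element a data.frame with columns
#'   \code{pos} and \code{allele}.
#' @param reference reference sequence (character scalar) or its length; used
#'   to validate positions and to distinguish private variants from the
#'   reference state. Alleles equal to the reference base at their position
#'   are rejected.
#' @return object of class \code{hg_defs}.
#' @export
hg_defs <- function(groups, reference) {
  stopifnot(is.list(groups), length(names(groups)) == length(groups))
  ref_chars <- NULL
  if (is.character(reference) && nchar(reference[1]) > 1) {
    ref_chars <- strsplit(as.character(reference)[1], "")[[1]]
    ref_len <- length(ref_chars)
  } else ref_len <- as.integer(reference)
  for (g in names(groups)) {
    d <- groups[[g]]
    if (!all(c("pos", "allele") %in% names(d)))
      stop("group ", g, " must have pos and allele columns")
    if (any(d$pos < 1 | d$pos > ref_len))
      stop("group ", g, " has defining positions outside the reference")
    if (!all(d$allele %in% c("A", "C", "G", "T")))
      stop("group ", g, " has non-ACGT defining alleles")
    if (!is.null(ref_chars) && any(d$allele == ref_chars[d$pos]))
      stop("group ", g, " has defining alleles equal to the reference base")
  }
  structure(list(groups = groups, reference = if (is.null(ref_chars)) NULL
                 else paste(ref_chars, collapse = ""),
                 reference_length = ref_len),
            class = "hg_defs")
}

#' @export
print.hg_defs <- function(x, ...) {
  cat(sprintf("hg_defs: %d haplogroup(s), %d defining variant(s), reference %d bp\n",
              length(x$groups), sum(vapply(x$groups, nrow, integer(1))),
              x$reference_length))
  invisible(x)
}

#' Write / read a haplogroup-definition file
#'
#' One line per haplogroup: name, a TAB, then comma-separated
#' \code{pos:allele} tokens.
#'
#' @param defs an \code{hg_defs}.
#' @param path file path.
#' @export
write_hg_defs <- function(defs, path) {
  stopifnot(inherits(defs, "hg_defs"))
  lines <- vapply(names(defs$groups), function(g) {
    d <- defs$groups[[g]]
    paste0(g, "\t", paste(sprintf("%d:%s", d$pos, d$allele), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hg_defs
#' @param reference reference sequence or length for validation.
#' @export
read_hg_defs <- function(path, reference) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  groups <- lapply(parts, function(p) {
    tok <- strsplit(p[2], ",", fixed = TRUE)[[1]]
    pa <- strsplit(tok, ":", fixed = TRUE)
    data.frame(pos = as.integer(vapply(pa, `[`, character(1), 1)),
               allele = vapply(pa, `[`, character(1), 2),
               stringsAsFactors = FALSE)
  })
  names(groups) <- vapply(parts, `[`, character(1), 1)
  hg_defs(groups, reference)
}

# accept DNAString/DNAStringSet element/character; return single-char vector
as_seq_chars <- function(s) {
  if (is.character(s) && length(s) > 1) return(s)
  strsplit(as.character(s), "")[[1]]
}

#' Score a query sequence against one haplogroup definition
#'
#' For each defining variant: an N in the query counts as missing, a query
#' base equal to the defining allele as matched, anything else as
#' mismatched. matched + mismatched + missing = |definition|.
#'
#' @param full_sequence full-length query (character scalar, character
#'   vector of bases, or \code{DNAString}).
#' @param group_definition data.frame with \code{pos} and \code{allele}.
#' @return named integer vector (matched, mismatched, missing).
#' @export
score_group <- function(full_sequence, group_definition) {
  q <- as_seq_chars(full_sequence)
  b <- q[group_definition$pos]
  missing <- sum(b == "N")
  matched <- sum(b == group_definition$allele & b != "N")
  c(matched = matched,
    mismatched = nrow(group_definition) - missing - matched,
    missing = missing)
}

common_prefix <- function(x) {
  if (length(x) == 1) return(x)
  chars <- strsplit(x, "")
  n <- min(lengths(chars))
  p <- 0L
  for (i in seq_len(n)) {
    if (length(unique(vapply(chars, `[`, character(1), i))) > 1) break
    p <- i
  }
  substr(x[1], 1, p)
}

#' Assign a haplogroup to one full-length sequence
#'
#' Each candidate group is scored by its match fraction
#' matched / (matched + mismatched) over non-missing defining sites (groups
#' with all defining sites missing are not candidates). The best-scoring
#' group wins; exact ties are reported as an unresolved tie list together
#' with the deepest common name prefix. A query matching no group at all
#' (all match fractions zero, or nothing scoreable) is unassignable.
#' Private variants are query bases differing from the reference at
#' positions that are defining variants of no group; missing variants are
#' the assigned group's defining variants at N positions.
#'
#' @param full_sequence full-length query sequence.
#' @param definitions an \code{hg_defs} with a reference sequence.
#' @param animal_id optional id carried into the call.
#' @return object of class \code{hg_call}: list with \code{animal_id},
#'   \code{group} (assigned name, common prefix for ties, or NA),
#'   \code{status} ("assigned", "tie", "unassignable"), \code{ties},
#'   \code{scores} (per-group data.frame), \code{missing_variants},
#'   \code{private_variants}.
#' @export
assign_haplogroup <- function(full_sequence, definitions, animal_id = NA) {
  stopifnot(inherits(definitions, "hg_defs"))
  if (length(definitions$groups) == 0) stop("definitions are empty")
  q <- as_seq_chars(full_sequence)
  if (length(q) != definitions$reference_length)
    stop("query length must equal the reference length")
  sc <- t(vapply(definitions$groups, function(g) score_group(q, g),
                 c(matched = 0L, mismatched = 0L, missing = 0L)))
  scored <- sc[, "matched"] + sc[, "mismatched"] >= 1
  frac <- ifelse(scored,
                 sc[, "matched"] / (sc[, "matched"] + sc[, "mismatched"]),
                 NA_real_)
  scores <- data.frame(group = rownames(sc), sc, fraction = frac,
                       row.names = NULL, stringsAsFactors = FALSE)
  if (!any(scored) || max(frac, na.rm = TRUE) == 0) {
    group <- NA_character_; status <- "unassignable"; ties <- character(0)
    assigned <- NULL
  } else {
    best <- max(frac, na.rm = TRUE)
    ties <- scores$group[!is.na(frac) & frac == best]
    if (length(ties) > 1) {
      group <- common_prefix(ties)
      status <- "tie"
    } else {
      group <- ties
      status <- "assigned"
    }
    assigned <- definitions$groups[[ties[1]]]
  }
  missing_variants <- if (is.null(assigned)) assigned else
    assigned[q[assigned$pos] == "N", , drop = FALSE]
  private_variants <- NULL
  if (!is.null(definitions$reference)) {
    ref <- strsplit(definitions$reference, "")[[1]]
    known <- unique(unlist(lapply(definitions$groups, `[[`, "pos")))
    cand <- which(q != "N" & q != ref & seq_along(q) <= length(ref))
    cand <- setdiff(cand, known)
    private_variants <- data.frame(pos = cand, allele = q[cand],
                                   stringsAsFactors = FALSE)
  }
  structure(list(animal_id = animal_id, group = group, status = status,
                 ties = if (length(ties) > 1) ties else character(0),
                 scores = scores,
                 missing_variants = missing_variants,
                 private_variants = private_variants),
            class = "hg_call")
}

#' @export
print.hg_call <- function(x, ...) {
  cat(sprintf("hg_call %s: %s (%s)%s\n",
              x$animal_id, x$group, x$status,
              if (length(x$ties)) paste0(" ties: ",
                                         paste(x$ties, collapse = "/"))
              else ""))
  invisible(x)
}

#' Assign haplogroups to a set of full-length sequences
#'
#' @param sequences \code{DNAStringSet} or named character vector of
#'   full-length sequences.
#' @param definitions an \code{hg_defs}.
#' @return list with \code{calls} (list of \code{hg_call}) and \code{table}
#'   (data.frame: animal, group, status, ties, score).
#' @export
assign_haplogroups <- function(sequences, definitions) {
  seqs <- as.character(sequences)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  calls <- lapply(seq_along(seqs), function(i)
    assign_haplogroup(seqs[i], definitions, animal_id = ids[i]))
  names(calls) <- ids
  tab <- data.frame(
    animal = ids,
    group = vapply(calls, function(x) x$group, character(1)),
    status = vapply(calls, function(x) x$status, character(1)),
    ties = vapply(calls, function(x)
      paste(x$ties, collapse = ","), character(1)),
    score = vapply(calls, function(x) {
      f <- x$scores$fraction
      if (all(is.na(f))) NA_real_ else max(f, na.rm = TRUE)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(calls = calls, table = tab)
}

#' Restrict haplogroup definitions to genomic intervals
#'
#' Keeps only defining variants inside the given 1-based inclusive
#' intervals (e.g. a D-loop-only mode, where the control region spans the
#' origin as a tail interval plus a head interval). Groups left without any
#' defining variant are flagged.
#'
#' @param definitions an \code{hg_defs}.
#' @param region_intervals list of \code{c(start, end)} pairs, or a
#'   two-column matrix.
#' @return an \code{hg_defs}; attribute \code{"empty_groups"} names groups
#'   with no variant left (retained with zero rows).
#' @export
restrict_to_region <- function(definitions, region_intervals) {
  stopifnot(inherits(definitions, "hg_defs"))
  if (is.matrix(region_intervals))
    region_intervals <- split(region_intervals, row(region_intervals))
  if (length(region_intervals) == 0) stop("region_intervals is empty")
  iv <- lapply(region_intervals, function(x) {
    x <- as.integer(x)
    if (length(x) != 2 || x[1] > x[2]) stop("invalid interval")
    if (x[1] < 1 || x[2] > definitions$reference_length)
      stop("interval outside the reference")
    x
  })
  inside <- function(p) Reduce(`|`, lapply(iv, function(x)
    p >= x[1] & p <= x[2]))
  groups <- lapply(definitions$groups, function(d)
    d[inside(d$pos), , drop = FALSE])
  out <- hg_defs(groups, if (is.null(definitions$reference))
    definitions$reference_length else definitions$reference)
  attr(out, "empty_groups") <-
    names(groups)[vapply(groups, nrow, integer(1)) == 0]
  out
}

#' Cattle D-loop region (control region around the origin)
#'
#' A configurable default for D-loop-only haplogrouping: the control region
#' spans the sequence origin, so it is the join of a tail interval and a
#' head interval (both 1-based inclusive).
#'
#' @param reference_length full reference length.
#' @param head_end last position of the head fragment.
#' @param tail_start first position of the tail fragment.
#' @return list of two intervals.
#' @export
dloop_region <- function(reference_length = 16340L, head_end = 363L,
                         tail_start = 15792L) {
  list(c(1L, as.integer(head_end)),
       c(as.integer(tail_start), as.integer(reference_length)))
}

#' Find private variants shared by subgroups of animals
#'
#' Within each assigned haplogroup, groups private variants by their exact
#' carrier set and reports every variant set carried by at least
#' \code{min_group_size} animals and by nobody else in that haplogroup —
#' the signature of an uncatalogued subgroup (e.g. a 64-animal set sharing
#' two private mutations within an indicine haplogroup). Optionally the
#' same search is stratified by breed.
#'
#' @param calls result of \code{\link{assign_haplogroups}} (or a list of
#'   \code{hg_call}).
#' @param metadata optional metadata; when given, member breeds are
#'   annotated and a per-breed search is added.
#' @param min_group_size minimum number of carriers.
#' @return data.frame: haplogroup, variants (comma-separated pos:allele),
#'   n_variants, n_members, members (comma-separated ids), breeds.
#' @export
find_shared_private_variants <- function(calls, metadata = NULL,
                                         min_group_size = 2L) {
  if (!is.null(calls$calls)) calls <- calls$calls
  assigned <- Filter(function(x) x$status %in% c("assigned", "tie"), calls)
  res <- list()
  by_group <- split(assigned, vapply(assigned, function(x) x$group,
                                     character(1)))
  for (g in names(by_group)) {
    cl <- by_group[[g]]
    carrier <- list()
    for (x in cl) {
      pv <- x$private_variants
      if (is.null(pv) || nrow(pv) == 0) next
      keys <- sprintf("%d:%s", pv$pos, pv$allele)
      for (k in keys) carrier[[k]] <- c(carrier[[k]], x$animal_id)
    }
    if (!length(carrier)) next
    sig <- vapply(carrier, function(m) paste(sort(m), collapse = "|"),
                  character(1))
    for (s in unique(sig)) {
      members <- sort(strsplit(s, "|", fixed = TRUE)[[1]])
      if (length(members) < min_group_size) next
      vars <- names(sig)[sig == s]
      ord <- order(as.integer(sub(":.*", "", vars)))
      breeds <- ""
      if (!is.null(metadata))
        breeds <- paste(sort(unique(
          metadata$breed[match(members, metadata$animal_id)])), collapse = ",")
      res[[length(res) + 1L]] <- data.frame(
        haplogroup = g, variants = paste(vars[ord], collapse = ","),
        n_variants = length(vars), n_members = length(members),
        members = paste(members, collapse = ","), breeds = breeds,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(haplogroup = character(0), variants = character(0),
                      n_variants = integer(0), n_members = integer(0),
                      members = character(0), breeds = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$haplogroup, -out$n_members), , drop = FALSE]
}
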