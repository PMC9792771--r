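# Edit descriptors and realized edited alleles.

#' Edit descriptors
#'
#' An edit descriptor records a single editing outcome relative to the
#' wild-type amplicon. Site indels are anchored to a cut coordinate:
#' insertions are inserted exactly at the cut, deletions of size `s` remove
#' `ceiling(s/2)` nt left of the cut and `floor(s/2)` nt right of it (the
#' convention used by the read simulator; the assay only reports total sizes).
#' Segment-level edits act on the whole inter-cut segment and carry no size.
#'
#' @param at for indels, which cut the edit is anchored to (`"cut1"` or
#'   `"cut2"`).
#' @param bases inserted bases (insertion) or the replacement base
#'   (substitution).
#' @param size deletion size in nt (positive number of removed bases).
#' @param position 0-based amplicon position of a substitution.
#' @return an object of class `edit_descriptor`.
#' @name edit_descriptor
NULL

new_edit <- function(kind, site, size = NA_integer_, detail = NA_character_,
                     position = NA_integer_) {
  structure(list(kind = kind, site = site, size = as.integer(size),
                 detail = detail, position = as.integer(position)),
            class = "edit_descriptor")
}

#' @rdname edit_descriptor
#' @export
edit_insertion <- function(at = c("cut1", "cut2"), bases) {
  at <- match.arg(at)
  assert_dna(bases, "inserted bases")
  if (nchar(bases) < 1L) stop("insertion must add at least one base", call. = FALSE)
  new_edit("insertion", at, size = nchar(bases), detail = bases)
}

#' @rdname edit_descriptor
#' @export
edit_deletion <- function(at = c("cut1", "cut2"), size) {
  at <- match.arg(at)
  size <- as.integer(size)
  if (is.na(size) || size == 0L) stop("deletion size must be non-zero", call. = FALSE)
  size <- abs(size)
  new_edit("deletion", at, size = -size)
}

#' @rdname edit_descriptor
#' @export
edit_segment_deletion <- function() new_edit("segment_deletion", "intercut")

#' @rdname edit_descriptor
#' @export
edit_segment_inversion <- function() new_edit("segment_inversion", "intercut")

#' @rdname edit_descriptor
#' @export
edit_substitution <- function(position, bases) {
  assert_dna(bases, "substituted base")
  if (nchar(bases) != 1L) stop("substitution replaces exactly one base", call. = FALSE)
  new_edit("substitution", "position", detail = bases, position = position)
}

#' @export
print.edit_descriptor <- function(x, ...) {
  desc <- switch(x$kind,
    insertion = sprintf("+%d nt (%s) at %s", x$size, x$detail, x$site),
    deletion = sprintf("%d nt at %s", x$size, x$site),
    segment_deletion = "inter-cut segment deleted",
    segment_inversion = "inter-cut segment inverted",
    substitution = sprintf("substitution ->%s at position %d", x$detail,
                           x$position))
  cat("<edit>", desc, "\n")
  invisible(x)
}

# leftmost amplicon coordinate an edit touches (for right-to-left application)
edit_anchor <- function(edit, pair) {
  cut <- function(site) if (site == "cut1") pair$cut1 else pair$cut2
  switch(edit$kind,
    insertion = cut(edit$site),
    deletion = cut(edit$site) - ceiling(abs(edit$size) / 2),
    segment_deletion = ,
    segment_inversion = pair$cut1,
    substitution = edit$position)
}

# half-open interval of amplicon positions removed/replaced by an edit
edit_footprint <- function(edit, pair) {
  cut <- function(site) if (site == "cut1") pair$cut1 else pair$cut2
  switch(edit$kind,
    insertion = {
      c(cut(edit$site), cut(edit$site))
    },
    deletion = {
      s <- abs(edit$size)
      c(cut(edit$site) - ceiling(s / 2), cut(edit$site) + floor(s / 2))
    },
    segment_deletion = ,
    segment_inversion = c(pair$cut1, pair$cut2),
    substitution = c(edit$position, edit$position + 1L))
}

#' Construct the realized sequence of an edited allele
#'
#' Applies a compatible set of edit descriptors to the wild-type amplicon.
#' At most one segment-level edit (inter-cut deletion or inversion) is
#' allowed; site edits must not fall inside a deleted segment and footprints
#' must not overlap. Edits are applied right-to-left so earlier coordinates
#' stay valid.
#'
#' @param amplicon an [amplicon()].
#' @param pair a [guide_pair()].
#' @param edits list of [edit_descriptor] objects (empty for wild type).
#' @param name allele label.
#' @return object of class `allele` with fields `name`, `edits`, `sequence`.
#' @export
build_allele <- function(amplicon, pair, edits = list(), name = "allele") {
  if (inherits(edits, "edit_descriptor")) edits <- list(edits)
  stopifnot(all(vapply(edits, inherits, logical(1), "edit_descriptor")))
  kinds <- vapply(edits, `[[`, character(1), "kind")
  n_segment <- sum(kinds %in% c("segment_deletion", "segment_inversion"))
  if (n_segment > 1L) stop("conflicting edits: more than one segment-level edit",
                           call. = FALSE)
  fps <- lapply(edits, edit_footprint, pair = pair)
  len <- nchar(amplicon$sequence)
  for (fp in fps)
    if (fp[1] < 0 || fp[2] > len)
      stop("conflicting edits: edit extends outside the amplicon", call. = FALSE)
  if (length(fps) > 1L) {
    ord <- order(vapply(fps, `[`, numeric(1), 1L))
    for (i in seq_len(length(ord) - 1L)) {
      a <- fps[[ord[i]]]; b <- fps[[ord[i + 1L]]]
      overlap <- max(a[1], b[1]) < min(a[2], b[2])
      abut_ins <- a[1] == a[2] && b[1] == b[2] && a[1] == b[1]
      if (overlap || abut_ins)
        stop("conflicting edits: overlapping footprints", call. = FALSE)
    }
  }
  if (any(kinds == "segment_deletion")) {
    seg <- c(pair$cut1, pair$cut2)
    for (i in seq_along(edits)) {
      if (kinds[i] %in% c("segment_deletion", "segment_inversion")) next
      fp <- fps[[i]]
      if (fp[1] >= seg[1] && fp[2] <= seg[2] &&
          !(fp[1] == fp[2] && (fp[1] == seg[1] || fp[1] == seg[2])))
        stop("conflicting edits: site edit inside deleted segment", call. = FALSE)
    }
  }

  seq <- amplicon$sequence
  ord <- order(vapply(edits, edit_anchor, numeric(1), pair = pair),
               decreasing = TRUE)
  for (e in edits[ord]) {
    seq <- apply_edit(seq, e, pair)
  }
  structure(list(name = name, edits = edits, sequence = seq),
            class = "allele")
}

apply_edit <- function(seq, edit, pair) {
  len <- nchar(seq)
  cut <- function(site) if (site == "cut1") pair$cut1 else pair$cut2
  switch(edit$kind,
    insertion = {
      c0 <- cut(edit$site)
      paste0(sub0(seq, 0, c0), edit$detail, sub0(seq, c0, len))
    },
    deletion = {
      fp <- edit_footprint(edit, pair)
      paste0(sub0(seq, 0, fp[1]), sub0(seq, fp[2], len))
    },
    segment_deletion = {
      paste0(sub0(seq, 0, pair$cut1), sub0(seq, pair$cut2, len))
    },
    segment_inversion = {
      paste0(sub0(seq, 0, pair$cut1),
             rc(sub0(seq, pair$cut1, pair$cut2)),
             sub0(seq, pair$cut2, len))
    },
    substitution = {
      p <- edit$position
      paste0(sub0(seq, 0, p), edit$detail, sub0(seq, p + 1L, len))
    })
}

#' @export
print.allele <- function(x, ...) {
  cat(sprintf("<allele> %s: %d bp, %d edit(s)\n", x$name, nchar(x$sequence),
              length(x$edits)))
  invisible(x)
}

#' Can each guide still cut an allele?
#'
#' A guide is cuttable iff its intact protospacer+PAM occurs in the allele
#' sequence on either strand (exact match). Inter-cut deletions and
#' inversions destroy both target sites; a site indel destroys only its own
#' guide's site.
#'
#' @param allele an `allele` (or a bare sequence string).
#' @param pair a [guide_pair()].
#' @return named logical vector, one element per guide.
#' @export
recut_check <- function(allele, pair) {
  seq <- if (inherits(allele, "allele")) allele$sequence else allele
  chk <- function(guide) {
    site <- paste0(guide$protospacer, guide$pam)
    count_occurrences(site, seq) + count_occurrences(rc(site), seq) > 0
  }
  c(stats::setNames(chk(pair$guide1), pair$guide1$name),
    stats::setNames(chk(pair$guide2), pair$guide2$name))
}
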