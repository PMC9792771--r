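# The analytical core: pair merging, template competition, split-mode
# classification, per-sample tabulation.

CATEGORIES <- c("wt", "indel", "large_deletion", "inversion",
                "substitution_only", "complex", "unclassified")

#' Merge paired-end reads by their best ungapped overlap
#'
#' R2 is reverse-complemented, then slid along R1; the highest-scoring
#' ungapped overlap of at least `min_overlap` nt with a mismatch fraction at
#' most `max_overlap_mismatch` is merged. Overlap disagreements are resolved
#' toward the base with higher quality, ties toward R1.
#'
#' @param r1,r2 data.frames with columns `id`, `seq`, `qual` (as produced by
#'   [simulate_reads()] / [read_fastq()]).
#' @param params a [caller_params()].
#' @return data.frame with columns `id`, `seq`, `qual`, `merged` (logical);
#'   unmerged pairs carry `NA` sequences.
#' @export
merge_pairs <- function(r1, r2, params = caller_params()) {
  stopifnot(nrow(r1) == nrow(r2))
  if (nrow(r1) == 0L)
    return(data.frame(id = character(), seq = character(), qual = character(),
                      merged = logical()))
  r2rc <- rc(r2$seq)
  q2rc <- reverse_strings_cpp(r2$qual)
  m <- merge_pairs_cpp(r1$seq, r2rc, r1$qual, q2rc,
                       params$min_overlap, params$max_overlap_mismatch)
  data.frame(id = r1$id, seq = m$seq, qual = m$qual, merged = m$merged)
}

# --- templates ---------------------------------------------------------------

# realized sequences of the structural allele models a read competes against
template_set <- function(amplicon, pair,
                         templates = c("wt", "large_deletion", "inversion")) {
  templates <- match.arg(templates, several.ok = TRUE)
  seqs <- c(
    wt = amplicon$sequence,
    large_deletion = build_allele(amplicon, pair,
                                  list(edit_segment_deletion()))$sequence,
    inversion = build_allele(amplicon, pair,
                             list(edit_segment_inversion()))$sequence)
  seqs[templates]
}

# junction coordinates monitored on each template
template_cuts <- function(pair, template) {
  switch(template,
         wt = c(pair$cut1, pair$cut2),
         large_deletion = pair$cut1,
         inversion = c(pair$cut1, pair$cut2))
}

empty_calls <- function() {
  data.frame(read_id = character(), category = character(),
             cut1_indel = integer(), cut2_indel = integer(),
             cut1_subs = integer(), cut2_subs = integer(),
             identity = numeric(), template = character())
}

# Classify unique merged sequences against the template set.
# Returns one row per input sequence.
classify_template_batch <- function(seqs, amplicon, pair, params,
                                    templates = c("wt", "large_deletion",
                                                  "inversion")) {
  tpl <- template_set(amplicon, pair, templates)
  n <- length(seqs)
  w <- params$quantification_window
  out <- data.frame(category = rep(NA_character_, n),
                    cut1_indel = rep(0L, n), cut2_indel = rep(0L, n),
                    cut1_subs = rep(0L, n), cut2_subs = rep(0L, n),
                    identity = rep(NA_real_, n),
                    template = rep(NA_character_, n))
  if (n == 0L) return(out)

  # ungapped screening against equal-length templates
  ham_id <- matrix(NA_real_, n, length(tpl),
                   dimnames = list(NULL, names(tpl)))
  ham_subs <- vector("list", length(tpl))
  names(ham_subs) <- names(tpl)
  for (t in names(tpl)) {
    hp <- hamming_profile_cpp(seqs, tpl[[t]],
                              as.integer(template_cuts(pair, t)), w)
    ok <- hp$mism >= 0L
    ham_id[ok, t] <- 1 - hp$mism[ok] / nchar(tpl[[t]])
    ham_subs[[t]] <- hp$subs
  }
  best_h <- apply(ham_id, 1, function(z) {
    i <- which(!is.na(z) & z >= params$fast_path_identity)
    if (length(i)) i[which.max(z[i])] else NA_integer_
  })
  fast <- which(!is.na(best_h))
  for (k in fast) {
    t <- names(tpl)[best_h[k]]
    out$identity[k] <- ham_id[k, t]
    out$template[k] <- t
    subs <- ham_subs[[t]][k, , drop = TRUE]
    cuts <- template_cuts(pair, t)
    out[k, c("cut1_subs", "cut2_subs")[seq_along(cuts)]] <- subs
    out$category[k] <- if (t == "wt") {
      if (any(subs > 0L)) "substitution_only" else "wt"
    } else t
  }

  slow <- setdiff(seq_len(n), fast)
  if (length(slow)) {
    # full affine alignment, winner by identity with ties broken in template
    # order (wt > large_deletion > inversion). A template is skipped for a
    # read when its identity upper bound min(n,m)/max(n,m) cannot beat the
    # best identity found so far (matches <= min(n,m), columns >= max(n,m)).
    nq <- nchar(seqs[slow])
    ids <- matrix(-Inf, length(slow), length(tpl))
    profs <- vector("list", length(tpl))
    prof_row <- matrix(NA_integer_, length(slow), length(tpl))
    best <- rep(-Inf, length(slow))
    for (ti in seq_along(tpl)) {
      t <- names(tpl)[ti]
      nt <- nchar(tpl[[t]])
      ub <- pmin(nq, nt) / pmax(nq, nt)
      todo <- which(ub > best)
      if (!length(todo)) { profs[[ti]] <- NULL; next }
      a <- gotoh_batch_cpp(seqs[slow[todo]], tpl[[t]], params$match,
                           params$mismatch, params$gap_open,
                           params$gap_extend)
      p <- aln_profile_cpp(a$query_aln, a$template_aln,
                           as.integer(template_cuts(pair, t)), w)
      ids[todo, ti] <- p$matches / p$columns
      best <- pmax(best, ids[, ti])
      profs[[ti]] <- p
      prof_row[todo, ti] <- seq_along(todo)
    }
    for (j in seq_along(slow)) {
      k <- slow[j]
      ti <- which.max(ids[j, ])        # first maximum = template priority
      t <- names(tpl)[ti]
      out$identity[k] <- ids[j, ti]
      if (ids[j, ti] < params$min_homology) {
        out$category[k] <- "unclassified"
        out$cut1_indel[k] <- NA_integer_
        out$cut2_indel[k] <- NA_integer_
        next
      }
      out$template[k] <- t
      p <- profs[[ti]]
      pj <- prof_row[j, ti]
      cuts <- template_cuts(pair, t)
      nev <- p$events[pj, , drop = TRUE]
      net <- p$indel[pj, , drop = TRUE]
      subs <- p$subs[pj, , drop = TRUE]
      if (t == "wt") {
        out$cut1_indel[k] <- net[1]
        out$cut2_indel[k] <- net[2]
        out$cut1_subs[k] <- subs[1]
        out$cut2_subs[k] <- subs[2]
        out$category[k] <- if (any(nev > 0L)) "indel"
          else if (any(subs > 0L)) "substitution_only" else "wt"
      } else {
        out[k, c("cut1_subs", "cut2_subs")[seq_along(cuts)]] <- subs
        out$category[k] <- if (any(nev > 0L)) "complex" else t
      }
    }
  }
  # fast-path reads can never fall below min_homology (>= fast_path_identity)
  out
}

# Split-mode classification of unique merged sequences (flank-anchored
# analog of spliced alignment + soft-clip inspection).
classify_split_batch <- function(seqs, amplicon, pair, params) {
  n <- length(seqs)
  out <- data.frame(category = rep(NA_character_, n),
                    cut1_indel = rep(0L, n), cut2_indel = rep(0L, n),
                    cut1_subs = rep(0L, n), cut2_subs = rep(0L, n),
                    identity = rep(NA_real_, n),
                    template = rep(NA_character_, n))
  if (n == 0L) return(out)
  wt <- amplicon$sequence
  c1 <- pair$cut1; c2 <- pair$cut2
  seg <- sub0(wt, c1, c2)
  segrc <- rc(seg)
  w <- params$quantification_window
  thr <- params$split_flank_min_identity

  a <- gotoh_batch_cpp(seqs, wt, params$match, params$mismatch,
                       params$gap_open, params$gap_extend)
  ss <- split_stats_cpp(a$query_aln, a$template_aln, c1, c2, w)
  p <- aln_profile_cpp(a$query_aln, a$template_aln, c(c1, c2), w)

  for (k in seq_len(n)) {
    lid <- ss$left_match[k] / ss$left_cols[k]
    rid <- ss$right_match[k] / ss$right_cols[k]
    flanks_ok <- lid >= thr && rid >= thr
    mid <- ss$middle[k]
    wt_identity <- p$matches[k] / p$columns[k]

    if (flanks_ok && ss$junction_deletion[k]) {
      out$category[k] <- "large_deletion"
      out$template[k] <- "large_deletion"
      out$identity[k] <- (ss$left_match[k] + ss$right_match[k]) /
        (ss$left_cols[k] + ss$right_cols[k])
      next
    }
    if (flanks_ok) {
      if (nchar(mid) == 0L) {
        out$category[k] <- "large_deletion"
        out$template[k] <- "large_deletion"
        out$identity[k] <- (ss$left_match[k] + ss$right_match[k]) /
          (ss$left_cols[k] + ss$right_cols[k])
        next
      }
      id_rc <- seq_identity(mid, segrc, params)
      if (id_rc >= thr) {
        out$category[k] <- "inversion"
        out$template[k] <- "inversion"
        out$identity[k] <- (ss$left_match[k] + ss$right_match[k] +
                              id_rc * nchar(segrc)) /
          (ss$left_cols[k] + ss$right_cols[k] + nchar(segrc))
        next
      }
      id_fw <- seq_identity(mid, seg, params)
      if (id_fw < thr) {
        out$category[k] <- "complex"
        out$template[k] <- "wt"
        out$identity[k] <- wt_identity
        next
      }
      # forward-orientation middle: fall through to the wt/indel path
    }
    out$identity[k] <- wt_identity
    if (wt_identity < params$min_homology) {
      out$category[k] <- "unclassified"
      out$cut1_indel[k] <- NA_integer_
      out$cut2_indel[k] <- NA_integer_
      next
    }
    out$template[k] <- "wt"
    nev <- p$events[k, , drop = TRUE]
    out$cut1_indel[k] <- p$indel[k, 1]
    out$cut2_indel[k] <- p$indel[k, 2]
    out$cut1_subs[k] <- p$subs[k, 1]
    out$cut2_subs[k] <- p$subs[k, 2]
    out$category[k] <- if (any(nev > 0L)) "indel"
      else if (any(p$subs[k, ] > 0L)) "substitution_only" else "wt"
  }
  out
}

#' Classify one merged read
#'
#' `classify_read` runs template competition: the read is aligned to the
#' wild-type, inter-cut-deletion and inter-cut-inversion templates; the
#' template with the highest identity wins (ties wt > large_deletion >
#' inversion) provided it reaches `min_homology`, and indels/substitutions
#' inside the quantification windows refine the category.
#' `classify_read_splitmode` instead anchors the read's flanks to the
#' amplicon outside the cut sites and inspects the unanchored middle — empty
#' middle means the large deletion (a splice-junction-style gap), a middle
#' matching the reverse complement of the inter-cut segment means the
#' inversion (the soft-clip signature).
#'
#' @param read merged read sequence (character).
#' @param amplicon an [amplicon()].
#' @param pair a [guide_pair()].
#' @param params a [caller_params()].
#' @param templates template labels to compete (subset of
#'   `c("wt", "large_deletion", "inversion")`; `"wt"` alone reproduces a
#'   single-template legacy caller).
#' @return one-row data.frame: `category`, `cut1_indel`, `cut2_indel`,
#'   `cut1_subs`, `cut2_subs`, `identity`, `template`.
#' @export
classify_read <- function(read, amplicon, pair, params = caller_params(),
                          templates = c("wt", "large_deletion", "inversion")) {
  classify_template_batch(read, amplicon, pair, params, templates)
}

#' @rdname classify_read
#' @export
classify_read_splitmode <- function(read, amplicon, pair,
                                    params = caller_params()) {
  classify_split_batch(read, amplicon, pair, params)
}

#' Call every read pair of a sample and tabulate editing outcomes
#'
#' Merges the pairs, classifies each merged read (template competition by
#' default), and tabulates per-category counts and fractions plus the
#' distinct-variant spectrum. Unmerged pairs are counted as unclassified.
#' Fractions are computed over classified reads; unclassified reads are
#' reported separately.
#'
#' @param reads a `read_set` (from [simulate_reads()]), or `r2` given
#'   separately.
#' @param r2 optional second-mate data.frame when `reads` is an R1
#'   data.frame.
#' @param amplicon an [amplicon()].
#' @param pair a [guide_pair()].
#' @param params a [caller_params()].
#' @param mode `"template"` (default) or `"split"`.
#' @param templates see [classify_read()].
#' @return object of class `allele_table`: list with `counts` (named, all
#'   categories), `total`, `classified`, `fractions` (over classified reads),
#'   `variants` (data.frame `variant`, `category`, `count`, `fraction`) and
#'   `calls` (per-read data.frame).
#' @export
call_sample <- function(reads, r2 = NULL, amplicon, pair,
                        params = caller_params(),
                        mode = c("template", "split"),
                        templates = c("wt", "large_deletion", "inversion")) {
  mode <- match.arg(mode)
  if (inherits(reads, "read_set")) {
    r1 <- reads$r1; r2 <- reads$r2
  } else {
    r1 <- reads
  }
  stopifnot(!is.null(r2))
  m <- merge_pairs(r1, r2, params)

  merged_idx <- which(m$merged)
  nr <- nrow(m)
  calls <- data.frame(read_id = m$id,
                      category = rep("unclassified", nr),
                      cut1_indel = rep(NA_integer_, nr),
                      cut2_indel = rep(NA_integer_, nr),
                      cut1_subs = rep(NA_integer_, nr),
                      cut2_subs = rep(NA_integer_, nr),
                      identity = rep(NA_real_, nr),
                      template = rep(NA_character_, nr))
  if (length(merged_idx)) {
    useq <- unique(m$seq[merged_idx])
    cls <- if (mode == "template")
      classify_template_batch(useq, amplicon, pair, params, templates)
    else
      classify_split_batch(useq, amplicon, pair, params)
    map <- match(m$seq[merged_idx], useq)
    calls[merged_idx, names(cls)] <- cls[map, ]
  }
  allele_table(calls)
}

variant_label <- function(calls) {
  lab <- calls$category
  ind <- which(calls$category == "indel")
  if (length(ind)) {
    lab[ind] <- vapply(ind, function(k) {
      parts <- character()
      if (!is.na(calls$cut1_indel[k]) && calls$cut1_indel[k] != 0L)
        parts <- c(parts, sprintf("cut1%+d", calls$cut1_indel[k]))
      if (!is.na(calls$cut2_indel[k]) && calls$cut2_indel[k] != 0L)
        parts <- c(parts, sprintf("cut2%+d", calls$cut2_indel[k]))
      if (!length(parts)) parts <- "0"
      paste0("indel:", paste(parts, collapse = ","))
    }, character(1))
  }
  sub <- which(calls$category == "substitution_only")
  if (length(sub)) {
    lab[sub] <- vapply(sub, function(k) {
      at <- c("cut1", "cut2")[c(calls$cut1_subs[k] > 0L,
                                calls$cut2_subs[k] > 0L)]
      paste0("substitution:", paste(at, collapse = ","))
    }, character(1))
  }
  lab
}

#' Tabulate per-read calls into an allele table
#' @param calls per-read call data.frame (see [call_sample()]).
#' @return an `allele_table`.
#' @export
allele_table <- function(calls) {
  counts <- vapply(CATEGORIES, function(cat) sum(calls$category == cat),
                   integer(1))
  total <- nrow(calls)
  classified <- total - counts[["unclassified"]]
  fractions <- if (classified > 0)
    counts[setdiff(CATEGORIES, "unclassified")] / classified
  else
    stats::setNames(rep(NA_real_, length(CATEGORIES) - 1L),
                    setdiff(CATEGORIES, "unclassified"))
  cl <- calls[calls$category != "unclassified", , drop = FALSE]
  if (nrow(cl)) {
    lab <- variant_label(cl)
    tab <- sort(table(lab), decreasing = TRUE)
    variants <- data.frame(variant = names(tab),
                           category = cl$category[match(names(tab), lab)],
                           count = as.integer(tab),
                           fraction = as.integer(tab) / classified)
  } else {
    variants <- data.frame(variant = character(), category = character(),
                           count = integer(), fraction = numeric())
  }
  structure(list(counts = counts, total = total, classified = classified,
                 fractions = fractions, variants = variants, calls = calls),
            class = "allele_table")
}

#' @export
print.allele_table <- function(x, ...) {
  cat(sprintf("<allele_table> %d reads (%d classified, %d unclassified)\n",
              x$total, x$classified, x$counts[["unclassified"]]))
  if (x$classified > 0) {
    f <- x$fractions[x$fractions > 0]
    for (nm in names(f))
      cat(sprintf("  %-18s %6.2f%%\n", nm, 100 * f[[nm]]))
  }
  invisible(x)
}

#' Write per-read calls / an allele table to disk
#'
#' @param table an `allele_table`.
#' @param calls_path TSV path for per-read calls.
#' @param json_path JSON path for the table summary.
#' @export
write_read_calls <- function(table, calls_path) {
  write.table(table$calls, calls_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(calls_path)
}

#' @rdname write_read_calls
#' @export
write_allele_table <- function(table, json_path) {
  jsonlite::write_json(
    list(total = table$total, classified = table$classified,
         counts = as.list(table$counts),
         fractions = as.list(table$fractions),
         variants = table$variants),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(json_path)
}
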