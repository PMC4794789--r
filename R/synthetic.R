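# Synthetic labeled alignments with planted column archetypes.
#
# The generator plants marginal column structure only (no evolution along
# a tree): invariant columns, conservation-band columns with an exact
# modal count drawn inside the band, group-specific columns (one residue
# fixed in the target group up to a substitution noise rate, a different
# residue dominant elsewhere), group-specific indel blocks (the stated
# group carries residues, everyone else a gap -- the "extended loop"
# situation), and background columns with moderate modal frequencies.
# Every column's archetype is recorded in a truth table so each pipeline
# stage has a recovery oracle.

# residue pairs biased toward readable group-specific reports
GS_PAIRS <- list(c("H", "L"), c("R", "F"), c("P", "E"), c("A", "G"))

#' Specification for a synthetic alignment
#'
#' Defaults emulate the NDP-sugar-dehydrogenase study conditions: four
#' groups of 92/55/38/44 sequences, 600 columns, 18 invariant columns,
#' 20 in the 80-99% band, 52 in the 60-79% band, a handful of
#' group-specific columns per group, and one gap block per group placed
#' at the loop positions reported for the family.
#'
#' @param group_sizes named integer vector, group name -> number of
#'   sequences (all at least 1).
#' @param n_columns alignment width.
#' @param n_invariant,n_band80,n_band60 planted column counts per band.
#' @param group_specific named integer vector, group -> number of planted
#'   group-specific columns.
#' @param gap_blocks list of `list(group =, start =, width =)` blocks;
#'   non-members of the group are gapped over the block.
#' @param within_group_noise substitution rate corrupting the fixed
#'   residue of group-specific columns inside the target group, in
#'   `[0, 1]`.
#' @param other_dominance frequency of the dominant residue outside the
#'   target group at group-specific columns (default 0.40); the remainder
#'   is drawn from the background.
#' @param background_modal_range half-open range `[lo, hi)` of
#'   modal-residue frequencies for background columns (default
#'   `c(0.30, 0.60)`), giving the moderate conservation typical of
#'   columns of a homologous family without entering the 60% band; the
#'   planted modal count is exact, so background columns never collide
#'   with the banded truth.
#' @param seed integer seed; one pseudorandom stream drives the whole
#'   generation, so equal seeds give byte-identical output.
#' @param shuffle place planted columns at random positions (default);
#'   with `FALSE` they are laid out contiguously in listed order
#'   (invariant, band80, band60, group-specific, background), which gives
#'   known conserved blocks for motif tests.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(group_sizes = c(UDPGDH_prok = 92L,
                                           UDPGDH_euk = 55L,
                                           UDPNAMDH = 38L,
                                           GDPMDH = 44L),
                           n_columns = 600L,
                           n_invariant = 18L, n_band80 = 20L,
                           n_band60 = 52L,
                           group_specific = c(UDPGDH_prok = 7L,
                                              UDPGDH_euk = 5L,
                                              UDPNAMDH = 9L,
                                              GDPMDH = 5L),
                           gap_blocks = list(
                             list(group = "UDPGDH_euk", start = 179L,
                                  width = 5L),
                             list(group = "GDPMDH", start = 202L,
                                  width = 5L),
                             list(group = "UDPNAMDH", start = 236L,
                                  width = 8L),
                             list(group = "GDPMDH", start = 386L,
                                  width = 2L)),
                           within_group_noise = 0.1,
                           other_dominance = 0.40,
                           background_modal_range = c(0.30, 0.60),
                           seed = 1L, shuffle = TRUE) {
  spec <- list(group_sizes = group_sizes, n_columns = as.integer(n_columns),
               n_invariant = as.integer(n_invariant),
               n_band80 = as.integer(n_band80),
               n_band60 = as.integer(n_band60),
               group_specific = group_specific, gap_blocks = gap_blocks,
               within_group_noise = within_group_noise,
               other_dominance = other_dominance,
               background_modal_range = background_modal_range,
               seed = as.integer(seed), shuffle = isTRUE(shuffle))
  problems <- character(0)
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    problems <- c(problems, "group_sizes must be named")
  }
  if (any(group_sizes < 1L)) problems <- c(problems, "group sizes must be >= 1")
  if (length(group_specific) &&
      !all(names(group_specific) %in% names(group_sizes))) {
    problems <- c(problems, "group_specific names must be declared groups")
  }
  gb_cols <- integer(0)
  for (b in gap_blocks) {
    if (!all(c("group", "start", "width") %in% names(b)) ||
        !b$group %in% names(group_sizes) ||
        b$start < 1L || b$start + b$width - 1L > n_columns) {
      problems <- c(problems, "malformed or out-of-range gap block")
    } else {
      gb_cols <- c(gb_cols, seq(b$start, length.out = b$width))
    }
  }
  if (anyDuplicated(gb_cols)) problems <- c(problems, "overlapping gap blocks")
  planted <- n_invariant + n_band80 + n_band60 + sum(group_specific) +
    length(gb_cols)
  if (planted > n_columns) {
    problems <- c(problems, sprintf(
      "planted columns (%d) exceed n_columns (%d)", planted, n_columns))
  }
  if (within_group_noise < 0 || within_group_noise > 1) {
    problems <- c(problems, "within_group_noise must be in [0, 1]")
  }
  if (length(problems)) {
    stop("invalid synthetic spec:\n  - ", paste(problems, collapse = "\n  - "))
  }
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic alignment spec: ", sum(x$group_sizes), " sequences (",
      paste(names(x$group_sizes), x$group_sizes, sep = "=", collapse = ", "),
      ") x ", x$n_columns, " columns\n", sep = "")
  cat("Planted: ", x$n_invariant, " invariant, ", x$n_band80, " band80, ",
      x$n_band60, " band60, ", sum(x$group_specific),
      " group-specific, ", length(x$gap_blocks), " gap blocks; noise ",
      x$within_group_noise, "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic labeled alignment with its truth table
#'
#' @param spec a [synthetic_spec()].
#' @return list with `alignment` (a [labeled_alignment()]), `truth`
#'   (data.frame: `col`, `archetype` in invariant/band80/band60/
#'   group_specific/gap_block/background, `group`, `residue`) and `spec`.
#' @examples
#' out <- generate_alignment(synthetic_spec(
#'   group_sizes = c(A = 10, B = 8), n_columns = 40, n_invariant = 4,
#'   n_band80 = 3, n_band60 = 3, group_specific = c(A = 2, B = 2),
#'   gap_blocks = list(), seed = 7))
#' band_summary(classify_columns(out$alignment))
#' @export
generate_alignment <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  sizes <- spec$group_sizes
  n <- sum(sizes)
  m <- spec$n_columns
  groups_per_row <- rep(names(sizes), times = sizes)
  ids <- unlist(lapply(names(sizes), function(g) {
    sprintf("%s_%03d", g, seq_len(sizes[[g]]))
  }), use.names = FALSE)

  # column layout
  arch <- rep("background", m)
  arch_group <- rep(NA_character_, m)
  gb_cols <- integer(0)
  for (b in spec$gap_blocks) {
    cols <- seq(b$start, length.out = b$width)
    arch[cols] <- "gap_block"
    arch_group[cols] <- b$group
    gb_cols <- c(gb_cols, cols)
  }
  pool <- setdiff(seq_len(m), gb_cols)
  plan <- c(rep("invariant", spec$n_invariant),
            rep("band80", spec$n_band80),
            rep("band60", spec$n_band60),
            unlist(lapply(names(spec$group_specific), function(g) {
              rep(g, spec$group_specific[[g]])
            }), use.names = FALSE))
  is_gs <- !plan %in% c("invariant", "band80", "band60")
  pos <- if (spec$shuffle) sample(pool, length(plan)) else
    pool[seq_along(plan)]
  arch[pos] <- ifelse(is_gs, "group_specific", plan)
  arch_group[pos[is_gs]] <- plan[is_gs]

  residue <- rep(NA_character_, m)
  mat <- matrix(NA_character_, n, m)
  band_bounds <- list(band80 = c(0.80, 1), band60 = c(0.60, 0.80))
  for (j in seq_len(m)) {
    a <- arch[j]
    if (a == "invariant") {
      res <- sample(AA20, 1L)
      mat[, j] <- res
      residue[j] <- res
    } else if (a %in% c("band80", "band60")) {
      res <- sample(AA20, 1L)
      lo <- band_bounds[[a]][1L]
      hi <- band_bounds[[a]][2L]
      k <- sample(seq(ceiling(lo * n), ceiling(hi * n) - 1L), 1L)
      colv <- sample(setdiff(AA20, res), n, replace = TRUE)
      colv[sample.int(n, k)] <- res
      mat[, j] <- colv
      residue[j] <- res
    } else if (a == "group_specific") {
      g <- arch_group[j]
      pair <- GS_PAIRS[[sample.int(length(GS_PAIRS), 1L)]]
      if (stats::runif(1) < 0.5) pair <- rev(pair)
      in_g <- groups_per_row == g
      colv <- character(n)
      # target group: fixed residue, corrupted at the noise rate
      tg <- rep(pair[1L], sum(in_g))
      flip <- stats::runif(sum(in_g)) < spec$within_group_noise
      tg[flip] <- sample(setdiff(AA20, pair[1L]), sum(flip), replace = TRUE)
      colv[in_g] <- tg
      # elsewhere: a different residue dominant, remainder background
      ot <- sample(setdiff(AA20, pair[2L]), sum(!in_g), replace = TRUE)
      dom <- stats::runif(sum(!in_g)) < spec$other_dominance
      ot[dom] <- pair[2L]
      colv[!in_g] <- ot
      mat[, j] <- colv
      residue[j] <- pair[1L]
    } else if (a == "gap_block") {
      g <- arch_group[j]
      in_g <- groups_per_row == g
      colv <- rep(GAP, n)
      colv[in_g] <- sample(AA20, sum(in_g), replace = TRUE)
      mat[, j] <- colv
    } else {
      lo <- max(1L, floor(spec$background_modal_range[1L] * n))
      hi <- min(ceiling(spec$background_modal_range[2L] * n) - 1L, n - 1L)
      k <- sample(seq(lo, max(lo, hi)), 1L)
      res <- sample(AA20, 1L)
      colv <- sample(setdiff(AA20, res), n, replace = TRUE)
      colv[sample.int(n, k)] <- res
      mat[, j] <- colv
    }
  }

  aln <- labeled_alignment(apply(mat, 1L, paste, collapse = ""),
                           ids = ids,
                           groups = stats::setNames(groups_per_row, ids))
  truth <- data.frame(col = seq_len(m), archetype = arch,
                      group = arch_group, residue = residue,
                      stringsAsFactors = FALSE)
  list(alignment = aln, truth = truth, spec = spec)
}

#' Recovery of planted group-specific columns
#'
#' For each group with planted group-specific columns, runs [gent_scan()]
#' and [rank_group_specific()] with `top_n` equal to the number of planted
#' columns, and scores precision and recall of the planted set.
#'
#' @param aln a generated [labeled_alignment()].
#' @param truth the matching truth table from [generate_alignment()].
#' @param bg,method scoring controls, as in [gent_scan()].
#' @param fe_cutoff forwarded to [rank_group_specific()] (default: median
#'   FE).
#' @return data.frame with one row per group (`group`, `n_planted`,
#'   `precision`, `recall`) plus a final `"overall"` row pooling all
#'   groups.
#' @export
planted_recovery <- function(aln, truth,
                             bg = background_frequencies("uniform"),
                             method = "kl", fe_cutoff = NULL) {
  gs <- truth[truth$archetype == "group_specific", , drop = FALSE]
  groups <- unique(gs$group)
  rows <- lapply(groups, function(g) {
    cols <- gs$col[gs$group == g]
    ranked <- rank_group_specific(gent_scan(aln, g, bg, method),
                                  fe_cutoff = fe_cutoff,
                                  top_n = length(cols))
    hit <- sum(ranked$col %in% cols)
    data.frame(group = g, n_planted = length(cols),
               precision = if (nrow(ranked)) hit / nrow(ranked) else 0,
               recall = hit / length(cols),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(
    group = "overall", n_planted = sum(out$n_planted),
    precision = sum(out$precision * out$n_planted) / sum(out$n_planted),
    recall = sum(out$recall * out$n_planted) / sum(out$n_planted)))
  rownames(out) <- NULL
  out
}

#' Write a truth table
#'
#' @param truth truth data.frame from [generate_alignment()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
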