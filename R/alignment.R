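# Labeled alignment container and format input/output.

# the 20 standard amino acids, alphabetical; modal residues and score
# distributions are defined over this set
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# ambiguity letters accepted on input; counted as "other" in profiles,
# excluded from score distributions
AA_AMBIG <- c("B", "Z", "X")

GAP <- "-"

# default group universe for the NDP-sugar-dehydrogenase use case
NDP_GROUPS <- c("UDPGDH_prok", "UDPGDH_euk", "GDPMDH", "UDPNAMDH")

#' Construct a labeled protein alignment
#'
#' An equal-length set of gapped protein sequences with unique ids and an
#' optional assignment of each sequence to a group. Gap glyphs `.` and `~`
#' are normalized to `-` and residues are uppercased.
#'
#' @param seqs character vector of aligned sequences (may be named by id).
#' @param ids sequence identifiers; defaults to `names(seqs)`.
#' @param groups named character vector mapping a subset of `ids` to group
#'   names; unassigned sequences get group `"unassigned"`.
#' @return An object of class `labeled_alignment` with elements `ids`,
#'   `seqs`, `groups` (named by id, always complete) and `n_columns`.
#' @examples
#' aln <- labeled_alignment(c(a = "MK-I", b = "MKLI"),
#'                          groups = c(a = "G1", b = "G2"))
#' aln$n_columns
#' @export
labeled_alignment <- function(seqs, ids = names(seqs), groups = NULL) {
  if (is.null(ids)) stop("sequence ids are required")
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  seqs <- gsub("[.~]", GAP, seqs)
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (length(seqs) < 1L) stop("alignment must contain at least one sequence")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  }
  if (any(!nzchar(ids))) stop("empty sequence id")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != lens[1L]][1L]
    stop("length mismatch: sequence '", bad, "' has ", nchar(seqs[ids == bad]),
         " columns, expected ", lens[1L])
  }
  if (lens[1L] < 1L) stop("alignment must have at least one column")
  allowed <- c(AA20, AA_AMBIG, GAP)
  letters_seen <- unique(strsplit(paste(seqs, collapse = ""), "")[[1L]])
  bad <- setdiff(letters_seen, allowed)
  if (length(bad)) stop("unknown residue letter '", bad[1L], "'")

  grp <- rep("unassigned", length(ids))
  names(grp) <- ids
  if (!is.null(groups)) {
    groups <- groups[!is.na(groups)]
    unknown <- setdiff(names(groups), ids)
    if (length(unknown)) {
      warning("group labels for ids absent from the alignment ignored: ",
              paste(utils::head(unknown, 3L), collapse = ", "))
      groups <- groups[names(groups) %in% ids]
    }
    grp[names(groups)] <- as.character(groups)
  }
  names(seqs) <- ids
  structure(list(ids = ids, seqs = seqs, groups = grp,
                 n_columns = unname(lens[1L])),
            class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat("Labeled protein alignment: ", length(x$ids), " sequences x ",
      x$n_columns, " columns\n", sep = "")
  tab <- table(x$groups)
  cat("Groups: ", paste(names(tab), unname(tab), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Group names declared in an alignment
#'
#' @param aln a [labeled_alignment()].
#' @param drop_unassigned drop the `"unassigned"` pseudo-group (default).
#' @return character vector of group names, in first-appearance order.
#' @export
declared_groups <- function(aln, drop_unassigned = TRUE) {
  g <- unique(aln$groups)
  if (drop_unassigned) g <- setdiff(g, "unassigned")
  g
}

# character matrix view, rows = sequences (named by id), columns = alignment
# columns
aln_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seqs, ""), use.names = FALSE),
              nrow = length(aln$ids), ncol = aln$n_columns, byrow = TRUE)
  rownames(m) <- aln$ids
  m
}

# integer-coded view: 1..20 = AA20, 0 = gap, 21 = ambiguity/other
aln_codes <- function(aln) {
  m <- aln_matrix(aln)
  codes <- match(m, AA20)
  codes[is.na(codes) & m == GAP] <- 0L
  codes[is.na(codes)] <- 21L
  dim(codes) <- dim(m)
  rownames(codes) <- aln$ids
  codes
}

#' Read a protein multiple sequence alignment
#'
#' Reads an aligned FASTA or GCG/MSF file into a [labeled_alignment()].
#' Residues are uppercased and the `.`/`~` gap glyphs are normalized to
#' `-`. MSF checksum fields are ignored on read.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"`, `"msf"`, or `"auto"` (decide from the file
#'   extension, falling back to content sniffing).
#' @return A [labeled_alignment()] with all sequences `"unassigned"`; attach
#'   labels with [set_groups()].
#' @seealso [write_alignment()]
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "msf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "msf") "msf"
      else if (ext %in% c("fa", "fasta", "afa", "fas", "aln")) "fasta"
      else if (any(grepl("MSF:", readLines(path, n = 20L)))) "msf"
      else "fasta"
  }
  if (format == "fasta") {
    recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               forceDNAtolower = FALSE)
    ids <- names(recs)
    seqs <- toupper(vapply(recs, function(r) r[[1L]], character(1L)))
  } else {
    a <- seqinr::read.alignment(path, format = "msf")
    ids <- a$nam
    seqs <- toupper(unlist(a$seq, use.names = FALSE))
  }
  out <- tryCatch(labeled_alignment(seqs, ids = ids),
                  error = function(e) e)
  if (inherits(out, "error")) {
    msg <- conditionMessage(out)
    bad <- regmatches(msg, regexec("unknown residue letter '(.)'", msg))[[1L]]
    if (length(bad) == 2L) {
      # locate the first file line carrying the offending letter for the
      # parse error the caller sees
      lines <- readLines(path, warn = FALSE)
      hit <- grep(bad[2L], lines, fixed = TRUE)[1L]
      stop(msg, " at line ", hit, " of ", path)
    }
    stop(msg)
  }
  out
}

#' Write an alignment to FASTA or MSF
#'
#' The MSF writer emits a GCG-style interleaved file with recomputed
#' checksums and `.` as the gap glyph; round-tripping through
#' [read_alignment()] restores `-` gaps.
#'
#' @param aln a [labeled_alignment()].
#' @param path output file path.
#' @param format `"fasta"` or `"msf"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "msf")) {
  format <- match.arg(format)
  if (format == "fasta") {
    seqinr::write.fasta(as.list(aln$seqs), names = aln$ids,
                        file.out = path, nbchar = 60)
    return(invisible(path))
  }
  seqs <- gsub(GAP, ".", aln$seqs, fixed = TRUE)
  cks <- vapply(seqs, gcg_checksum, numeric(1L))
  total <- sum(cks) %% 10000
  width <- max(nchar(aln$ids)) + 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("PileUp", ""), con)
  writeLines(sprintf(" MSF: %d  Type: P  Check: %d ..", aln$n_columns, total),
             con)
  writeLines("", con)
  for (i in seq_along(aln$ids)) {
    writeLines(sprintf(" Name: %s  Len: %d  Check: %d  Weight: 1.00",
                       formatC(aln$ids[i], width = -width), aln$n_columns,
                       cks[i]), con)
  }
  writeLines(c("", "//", ""), con)
  starts <- seq(1L, aln$n_columns, by = 50L)
  for (s in starts) {
    e <- min(s + 49L, aln$n_columns)
    for (i in seq_along(aln$ids)) {
      chunk <- substring(seqs[i], seq(s, e, by = 10L),
                         pmin(seq(s, e, by = 10L) + 9L, e))
      writeLines(paste0(formatC(aln$ids[i], width = -width), "  ",
                        paste(chunk, collapse = " ")), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

# GCG sequence checksum (mod 10000)
gcg_checksum <- function(seq) {
  ch <- utf8ToInt(toupper(seq))
  idx <- seq_along(ch) - 1L
  sum((idx %% 57L + 1L) * ch) %% 10000
}

#' Read a sequence-to-group label table
#'
#' Two-column tab-separated text (`id<TAB>group`), header optional. A
#' duplicated id is tolerated when its group agrees and is an error
#' otherwise.
#'
#' @param path path to the TSV file.
#' @param valid_groups allowed group names; defaults to the four
#'   NDP-sugar-dehydrogenase groups plus `"unassigned"`. Use `NULL` to
#'   accept any name.
#' @return named character vector (id -> group); empty input gives an
#'   empty vector (every sequence then defaults to `"unassigned"` when
#'   applied with [set_groups()]).
#' @export
read_group_labels <- function(path,
                              valid_groups = c(NDP_GROUPS, "unassigned")) {
  if (!file.exists(path)) stop("group-label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("malformed label line ", bad[1L], ": ", lines[bad[1L]])
  ids <- trimws(vapply(parts, `[[`, character(1L), 1L))
  grp <- trimws(vapply(parts, `[[`, character(1L), 2L))
  if (tolower(ids[1L]) %in% c("id", "sequence", "seqid", "name") &&
      tolower(grp[1L]) %in% c("group", "label")) {
    ids <- ids[-1L]
    grp <- grp[-1L]
  }
  if (!length(ids)) return(stats::setNames(character(0), character(0)))
  if (!is.null(valid_groups)) {
    unknown <- setdiff(unique(grp), valid_groups)
    if (length(unknown)) {
      stop("unknown group name(s): ", paste(unknown, collapse = ", "))
    }
  }
  first <- !duplicated(ids)
  if (any(!first)) {
    for (id in unique(ids[!first])) {
      g <- unique(grp[ids == id])
      if (length(g) > 1L) {
        stop("conflicting group for id '", id, "': ",
             paste(g, collapse = " vs "))
      }
    }
  }
  stats::setNames(grp[first], ids[first])
}

#' Attach group labels to an alignment
#'
#' @param aln a [labeled_alignment()].
#' @param labels named character vector (id -> group), e.g. from
#'   [read_group_labels()].
#' @return the alignment with its `groups` replaced; ids absent from
#'   `labels` become `"unassigned"`.
#' @export
set_groups <- function(aln, labels) {
  stopifnot(inherits(aln, "labeled_alignment"))
  labeled_alignment(aln$seqs, ids = aln$ids, groups = labels)
}

#' Write a group-label table
#'
#' @param aln a [labeled_alignment()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_group_labels <- function(aln, path) {
  utils::write.table(data.frame(id = aln$ids, group = unname(aln$groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
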