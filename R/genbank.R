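# GenBank flat-file I/O.
#
# The parser targets the subset of the format carried by annotated bacterial
# RefSeq records and by the synthetic-panel writer: LOCUS / FEATURES / ORIGIN
# blocks, feature keys at column 6, locations with complement() / join() /
# order() nesting and <...> partial markers, quoted and bare qualifiers.
# Coordinates are converted from GenBank 1-based inclusive to the plus strand
# at this boundary; everything downstream works with strand-aware sense
# sequences.

#' Read annotated genomes from GenBank flat files
#'
#' Parses one or more GenBank records (multi-replicon genomes are supplied as
#' multiple records or multiple files) into a single `annotated_genome`
#' object: tibbles of coding genes, tRNA genes and rRNA genes, plus
#' genome-level composition statistics. All features are extracted
#' strand-correctly; pseudogenes are flagged (not dropped); compound
#' `join()` locations are resolved.
#'
#' @param paths Character vector of GenBank flat-file paths (optionally
#'   gzipped, detected by `.gz` suffix).
#' @param species Species label; defaults to the definition/locus name of the
#'   first record.
#' @param rank_gt Optional generation-time rank (positive integer) attached
#'   to the genome metadata.
#' @param upstream_length,downstream_length Number of nucleotides of
#'   strand-aware context extracted 5' of the start codon and 3' of the stop
#'   codon (defaults 60; shorter only at replicon edges).
#' @return An `annotated_genome`: a list with `meta` (species, rank_gt,
#'   accessions), `replicons`, `genes`, `trna`, `rrna` tibbles and the summary
#'   fields `genome_length`, `gc_percent`, `rrn_count`, `trna_count`, `n_cds`
#'   (coding genes after pseudogene exclusion).
#' @seealso [count_rrn_operons()], [classify_expression()], [feature_table()]
#' @export
read_genbank <- function(paths, species = NULL, rank_gt = NA_integer_,
                         upstream_length = 60L, downstream_length = 60L) {
  records <- purrr::list_flatten(purrr::map(paths, read_gb_records))
  if (length(records) == 0) abort("no GenBank records found")
  build_annotated_genome(records, species = species, rank_gt = rank_gt,
                         upstream_length = upstream_length,
                         downstream_length = downstream_length)
}

# -- low-level record parsing -------------------------------------------------

read_gb_records <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  ends <- which(lines == "//")
  if (length(ends) == 0) {
    abort(paste0("malformed GenBank file (no record terminator '//'): ", path))
  }
  starts <- c(1L, head(ends, -1) + 1L)
  purrr::map2(starts, ends, function(s, e) {
    parse_gb_record(lines[s:(e - 1L)], path)
  })
}

parse_gb_record <- function(lines, path = "<text>") {
  lines <- lines[nzchar(lines)]
  locus_i <- which(startsWith(lines, "LOCUS"))
  feat_i <- which(startsWith(lines, "FEATURES"))
  orig_i <- which(startsWith(lines, "ORIGIN"))
  if (length(locus_i) != 1 || length(feat_i) != 1 || length(orig_i) != 1) {
    abort(paste0("malformed GenBank record in ", path,
                 ": need exactly one LOCUS, FEATURES and ORIGIN line"))
  }
  accession <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i])), "\\s+")[[1]][1]
  def_i <- which(startsWith(lines, "DEFINITION"))
  definition <- if (length(def_i)) trimws(sub("^DEFINITION", "", lines[def_i[1]])) else accession

  seq_lines <- lines[(orig_i + 1L):length(lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feats <- parse_gb_features(lines[(feat_i + 1L):(orig_i - 1L)], accession)
  list(accession = accession, definition = definition,
       sequence = sequence, features = feats)
}

parse_gb_features <- function(flines, accession) {
  is_key <- grepl("^ {5}\\S", flines)
  key_idx <- which(is_key)
  if (length(key_idx) == 0) {
    return(list())
  }
  block_end <- c(key_idx[-1] - 1L, length(flines))
  purrr::map2(key_idx, block_end, function(s, e) {
    key <- trimws(substr(flines[s], 1, 21))
    body <- trimws(c(substring(flines[s], 22), if (e > s) trimws(flines[(s + 1):e])))
    qual_start <- which(startsWith(body, "/"))
    loc_lines <- if (length(qual_start)) body[seq_len(qual_start[1] - 1L)] else body
    location <- paste(loc_lines, collapse = "")
    quals <- list()
    if (length(qual_start)) {
      qends <- c(qual_start[-1] - 1L, length(body))
      for (k in seq_along(qual_start)) {
        q <- paste(body[qual_start[k]:qends[k]], collapse = " ")
        m <- regmatches(q, regexec("^/([A-Za-z_0-9]+)(=(.*))?$", q))[[1]]
        if (length(m) == 0) next
        val <- m[4]
        if (is.na(val) || val == "") val <- TRUE else val <- gsub("^\"|\"$", "", val)
        quals[[m[2]]] <- val
      }
    }
    list(key = key, location = location, qualifiers = quals,
         accession = accession)
  })
}

# Parse a GenBank location string into segments + strand.
# Returns list(strand = "+"/"-", segments = data.frame(start, end),
# partial = TRUE/FALSE). Segments are in the order listed; for complement()
# the concatenation of listed segments is reverse-complemented.
parse_gb_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  partial <- grepl("[<>]", loc)
  loc2 <- gsub("[<>]", "", loc)
  rec <- function(s, strand) {
    if (startsWith(s, "complement(")) {
      inner <- substr(s, 12L, nchar(s) - 1L)
      return(rec(inner, if (strand == "+") "-" else "+"))
    }
    if (startsWith(s, "join(") || startsWith(s, "order(")) {
      inner <- sub("^[a-z]+\\(", "", s)
      inner <- substr(inner, 1L, nchar(inner) - 1L)
      parts <- split_toplevel(inner)
      segs <- do.call(rbind, lapply(parts, function(p) rec(p, "+")$segments))
      return(list(strand = strand, segments = segs))
    }
    m <- regmatches(s, regexec("^(\\d+)(\\.\\.(\\d+))?$", s))[[1]]
    if (length(m) == 0) abort(paste0("cannot parse GenBank location: ", loc))
    a <- as.integer(m[2])
    b <- if (is.na(m[4]) || m[4] == "") a else as.integer(m[4])
    list(strand = strand, segments = data.frame(start = a, end = b))
  }
  out <- rec(loc2, "+")
  out$partial <- partial
  out
}

# split "a..b,complement(c..d)" at top-level commas only
split_toplevel <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  cuts <- which(chars == "," & depth == 0)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  mapply(function(a, b) paste(chars[a:b], collapse = ""), starts, ends)
}

extract_feature_seq <- function(sequence, locinfo) {
  segs <- locinfo$segments
  parts <- substring(sequence, segs$start, segs$end)
  s <- paste(parts, collapse = "")
  if (locinfo$strand == "-") s <- revcomp(s) else s
}

# -- genome assembly ----------------------------------------------------------

build_annotated_genome <- function(records, species, rank_gt,
                                   upstream_length, downstream_length) {
  if (is.null(species)) species <- records[[1]]$definition
  replicons <- tibble::tibble(
    accession = purrr::map_chr(records, "accession"),
    length = purrr::map_int(records, ~ nchar(.x$sequence)),
    sequence = purrr::map_chr(records, "sequence")
  )

  feats <- purrr::list_flatten(purrr::map(records, "features"))
  keys <- purrr::map_chr(feats, "key")

  genes <- extract_cds(feats[keys == "CDS"], replicons,
                       upstream_length, downstream_length)
  trna <- extract_trna(feats[keys == "tRNA"])
  rrna <- extract_rrna(feats[keys == "rRNA"])

  genome_seq_gc <- gc_percent(replicons$sequence)
  g <- structure(list(
    meta = list(species = species, rank_gt = as.integer(rank_gt),
                accessions = replicons$accession),
    replicons = replicons,
    genes = genes,
    trna = trna,
    rrna = rrna,
    genome_length = sum(replicons$length),
    gc_percent = genome_seq_gc,
    trna_count = nrow(trna),
    n_cds = sum(!genes$is_pseudo)
  ), class = "annotated_genome")
  g$rrn_count <- count_rrn_operons(g, quiet = TRUE)
  g
}

extract_cds <- function(feats, replicons, upstream_length, downstream_length) {
  if (length(feats) == 0) {
    return(tibble::tibble(
      locus_tag = character(), gene = character(), replicon = character(),
      start = integer(), end = integer(), strand = character(),
      is_pseudo = logical(), length_ok = logical(), cds = character(),
      upstream = character(), downstream = character(),
      start_codon = character(), stop_codon = character(),
      gc = double(), class = character()
    ))
  }
  rows <- purrr::map(feats, function(f) {
    locinfo <- parse_gb_location(f$location)
    seqs <- replicons$sequence[match(f$accession, replicons$accession)]
    L <- nchar(seqs)
    cds <- extract_feature_seq(seqs, locinfo)
    lo <- min(locinfo$segments$start); hi <- max(locinfo$segments$end)
    if (locinfo$strand == "+") {
      up <- substr(seqs, max(1L, lo - upstream_length), lo - 1L)
      dn <- substr(seqs, hi + 1L, min(L, hi + downstream_length))
    } else {
      up <- revcomp(substr(seqs, hi + 1L, min(L, hi + upstream_length)))
      dn <- revcomp(substr(seqs, max(1L, lo - downstream_length), lo - 1L))
    }
    q <- f$qualifiers
    is_pseudo <- isTRUE(q$pseudo) || isTRUE(q$pseudogene) ||
      (!is.null(q$pseudogene) && !isFALSE(q$pseudogene))
    tibble::tibble(
      locus_tag = q$locus_tag %||% NA_character_,
      gene = q$gene %||% NA_character_,
      replicon = f$accession, start = lo, end = hi,
      strand = locinfo$strand, is_pseudo = is_pseudo,
      length_ok = nchar(cds) %% 3L == 0L && !locinfo$partial,
      cds = cds, upstream = up, downstream = dn
    )
  })
  genes <- dplyr::bind_rows(rows)
  if (any(!genes$length_ok & !genes$is_pseudo)) {
    warn(sprintf("%d CDS with length not a multiple of 3 (or partial); flagged via length_ok",
                 sum(!genes$length_ok & !genes$is_pseudo)))
  }
  genes |>
    dplyr::mutate(
      start_codon = substr(.data$cds, 1L, 3L),
      stop_codon = substr(.data$cds, nchar(.data$cds) - 2L, nchar(.data$cds)),
      gc = gc_percent_each(.data$cds),
      class = NA_character_
    )
}

extract_trna <- function(feats) {
  if (length(feats) == 0) {
    return(tibble::tibble(locus_tag = character(), amino_acid = character(),
                          anticodon = character()))
  }
  dplyr::bind_rows(purrr::map(feats, function(f) {
    q <- f$qualifiers
    product <- q$product %||% ""
    aa <- sub("^tRNA-", "", product)
    anticodon <- NA_character_
    if (!is.null(q$anticodon)) {
      m <- regmatches(q$anticodon, regexec("seq:([A-Za-z]+)", q$anticodon))[[1]]
      if (length(m) == 2) anticodon <- toupper(as_rna(m[2]))
    }
    tibble::tibble(locus_tag = q$locus_tag %||% NA_character_,
                   amino_acid = aa, anticodon = anticodon)
  }))
}

extract_rrna <- function(feats) {
  if (length(feats) == 0) {
    return(tibble::tibble(locus_tag = character(), product = character(),
                          subunit = character()))
  }
  dplyr::bind_rows(purrr::map(feats, function(f) {
    product <- f$qualifiers$product %||% ""
    subunit <- dplyr::case_when(
      grepl("16S", product) ~ "16S",
      grepl("23S", product) ~ "23S",
      grepl("\\b5S", product) ~ "5S",
      TRUE ~ NA_character_
    )
    tibble::tibble(locus_tag = f$qualifiers$locus_tag %||% NA_character_,
                   product = product, subunit = subunit)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome> ", x$meta$species, "\n", sep = "")
  cat(sprintf("  replicons: %d  length: %d nt  GC%%: %.2f\n",
              nrow(x$replicons), x$genome_length, x$gc_percent))
  cat(sprintf("  CDS: %d (%d pseudo)  tRNA: %d  rrn (16S): %d\n",
              nrow(x$genes), sum(x$genes$is_pseudo), x$trna_count, x$rrn_count))
  invisible(x)
}

#' One-row summary of an annotated genome
#'
#' @param x An `annotated_genome`.
#' @param ... Unused.
#' @return A tibble with species, rank_gt, genome_length, n_cds, rrn_count,
#'   trna_count and gc_percent.
#' @export
glance.annotated_genome <- function(x, ...) {
  tibble::tibble(
    species = x$meta$species, rank_gt = x$meta$rank_gt,
    genome_length = x$genome_length, n_cds = x$n_cds,
    rrn_count = x$rrn_count, trna_count = x$trna_count,
    gc_percent = x$gc_percent
  )
}

# -- writer (used by the synthetic-panel generator) ---------------------------

#' Write a GenBank flat file
#'
#' Serialises one replicon (sequence plus a feature table) as a GenBank
#' record re-readable by [read_genbank()]. Used by the synthetic-panel
#' generator; not a general-purpose round-trip of arbitrary records.
#'
#' @param accession Replicon accession/locus name.
#' @param definition Definition line text.
#' @param sequence Plus-strand DNA string.
#' @param features Tibble with columns `key`, `start`, `end`, `strand` and a
#'   list-column `qualifiers` of named lists (logical `TRUE` for flag
#'   qualifiers such as `/pseudo`).
#' @param path Output file; opened in append mode when `append = TRUE` so
#'   multi-replicon genomes can share a file.
#' @param append Append to an existing file?
#' @return `path`, invisibly.
#' @export
write_genbank <- function(accession, definition, sequence, features, path,
                          append = FALSE) {
  out <- character(0)
  out <- c(out, sprintf("LOCUS       %s %d bp    DNA     circular BCT",
                        accession, nchar(sequence)))
  out <- c(out, paste0("DEFINITION  ", definition))
  out <- c(out, "FEATURES             Location/Qualifiers")
  out <- c(out, sprintf("     %-16s%s", "source",
                        sprintf("1..%d", nchar(sequence))))
  if (nrow(features)) {
    for (i in seq_len(nrow(features))) {
      loc <- sprintf("%d..%d", features$start[i], features$end[i])
      if (features$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      out <- c(out, sprintf("     %-16s%s", features$key[i], loc))
      q <- features$qualifiers[[i]]
      for (nm in names(q)) {
        v <- q[[nm]]
        out <- c(out, if (isTRUE(v)) {
          sprintf("                     /%s", nm)
        } else if (is.numeric(v)) {
          sprintf("                     /%s=%s", nm, format(v))
        } else {
          sprintf("                     /%s=\"%s\"", nm, v)
        })
      }
    }
  }
  out <- c(out, "ORIGIN")
  n <- nchar(sequence)
  starts <- seq(1L, n, by = 60L)
  seq_lines <- vapply(starts, function(s) {
    chunk <- substr(sequence, s, min(n, s + 59L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(nchar(chunk), seq(10, nchar(chunk) + 9, 10)))
    sprintf("%9d %s", s, paste(tolower(groups), collapse = " "))
  }, character(1))
  out <- c(out, seq_lines, "//")
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
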