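#' Parse annotated mitogenome features
#'
#' Reads per-gene feature annotations from either a simplified TSV or a
#' GenBank flat file and returns one row per feature. Coordinates are
#' 1-based inclusive on input (the GenBank convention). A feature whose
#' start exceeds its end is taken to wrap the circular origin and gets the
#' \code{wrap} flag; its length is computed modulo the genome length.
#'
#' The TSV layout is \code{sample_id, raw_name, start, end, strand,
#' feature_class[, anticodon]} with a header row; \code{strand} is
#' \code{+}/\code{-} and \code{feature_class} one of \code{gene},
#' \code{tRNA}, \code{rRNA}, \code{D-loop}, \code{origin}, \code{other}.
#'
#' The GenBank reader handles the feature-table subset relevant here:
#' \code{gene}, \code{CDS}, \code{tRNA}, \code{rRNA}, \code{D-loop},
#' \code{rep_origin} and \code{misc_feature} keys, \code{complement()}
#' locations, two-segment \code{join()} locations wrapping the origin, and
#' the \code{/gene}, \code{/product} and \code{/anticodon} qualifiers.
#' \code{gene} keys duplicating a \code{CDS}/\code{tRNA}/\code{rRNA} span
#' are dropped in favour of the typed feature.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"genbank"}.
#' @return data.frame with columns \code{sample_id}, \code{raw_name},
#'   \code{start}, \code{end}, \code{strand} (+1/-1),
#'   \code{feature_class}, \code{anticodon}, \code{wrap}, \code{length};
#'   attribute \code{genome_length} (GenBank, per sample) when known.
#' @export
parse_features <- function(path, format = c("tsv", "genbank")) {
  format <- match.arg(format)
  switch(format,
         tsv = parse_features_tsv(path),
         genbank = parse_features_genbank(path))
}

parse_features_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "raw_name", "start", "end", "strand", "feature_class")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("malformed TSV ", path, ": missing columns ",
         paste(miss, collapse = ", "))
  }
  if (!"anticodon" %in% names(tab)) tab$anticodon <- NA_character_
  bad <- which(!tab$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    stop(sprintf("malformed TSV %s: bad strand in data row %d", path, bad[1]))
  }
  if (any(tab$start < 1)) stop("malformed TSV ", path, ": start < 1")
  out <- data.frame(
    sample_id = tab$sample_id, raw_name = tab$raw_name,
    start = as.integer(tab$start), end = as.integer(tab$end),
    strand = ifelse(tab$strand == "-", -1L, 1L),
    feature_class = tab$feature_class,
    anticodon = as.character(tab$anticodon),
    stringsAsFactors = FALSE)
  out$wrap <- out$start > out$end
  out$length <- ifelse(out$wrap, NA_integer_, out$end - out$start + 1L)
  out
}

parse_features_genbank <- function(path) {
  lines <- readLines(path)
  keep_keys <- c(gene = "gene", CDS = "gene", tRNA = "tRNA", rRNA = "rRNA",
                 "D-loop" = "D-loop", rep_origin = "origin",
                 misc_feature = "other")
  recs <- list()
  sample_id <- NA_character_; genome_length <- NA_integer_
  cur <- NULL; in_features <- FALSE
  lengths <- c()
  flush <- function() {
    if (!is.null(cur)) recs[[length(recs) + 1L]] <<- cur
    cur <<- NULL
  }
  for (k in seq_along(lines)) {
    line <- lines[k]
    if (startsWith(line, "LOCUS")) {
      f <- strsplit(trimws(line), "[[:space:]]+")[[1]]
      sample_id <- f[2]
      genome_length <- suppressWarnings(as.integer(f[3]))
      if (is.na(genome_length)) {
        stop(sprintf("malformed GenBank %s: bad LOCUS at line %d", path, k))
      }
      lengths[sample_id] <- genome_length
      in_features <- FALSE
      next
    }
    if (startsWith(line, "FEATURES")) { in_features <- TRUE; next }
    if (startsWith(line, "ORIGIN") || startsWith(line, "//")) {
      flush(); in_features <- FALSE; next
    }
    if (!in_features) next
    if (grepl("^ {5}[A-Za-z]", line)) {          # new feature key
      flush()
      key <- trimws(substr(line, 6, 20))
      loc <- trimws(substr(line, 21, nchar(line)))
      if (!key %in% names(keep_keys)) next
      p <- parse_gb_location(loc, genome_length, path, k)
      cur <- data.frame(
        sample_id = sample_id, raw_name = NA_character_,
        start = p$start, end = p$end, strand = p$strand,
        feature_class = unname(keep_keys[key]), gb_key = key,
        anticodon = NA_character_, wrap = p$wrap,
        stringsAsFactors = FALSE)
    } else if (!is.null(cur) && grepl("^ {21}/", line)) {
      q <- sub("^ +/", "", line)
      val <- sub('^[^=]*=?"?', "", q); val <- sub('"$', "", val)
      if (startsWith(q, "gene=")) {
        cur$raw_name <- val
      } else if (startsWith(q, "product=") && is.na(cur$raw_name)) {
        cur$raw_name <- val
      } else if (startsWith(q, "anticodon=")) {
        m <- regmatches(val, regexpr("seq:[a-zA-Z]+", val))
        if (length(m) == 1) cur$anticodon <- toupper(sub("seq:", "", m))
      }
    }
  }
  flush()
  if (length(recs) == 0) stop("malformed GenBank ", path, ": no features")
  out <- do.call(rbind, recs)
  # drop bare `gene` keys that duplicate a typed feature's span
  typed <- out$gb_key != "gene"
  dup <- out$gb_key == "gene" &
    paste(out$sample_id, out$start, out$end) %in%
      paste(out$sample_id, out$start, out$end)[typed]
  out <- out[!dup, ]
  out$gb_key <- NULL
  out <- out[!is.na(out$raw_name) | out$feature_class %in%
               c("D-loop", "origin"), ]
  out$raw_name[is.na(out$raw_name)] <- out$feature_class[is.na(out$raw_name)]
  gl <- lengths[out$sample_id]
  out$length <- ifelse(out$wrap, gl - out$start + 1L + out$end,
                       out$end - out$start + 1L)
  rownames(out) <- NULL
  attr(out, "genome_length") <- lengths
  out
}

parse_gb_location <- function(loc, genome_length, path, lineno) {
  strand <- 1L
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wrap <- FALSE
  if (grepl("^join\\(", loc)) {
    segs <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
    if (length(segs) != 2) {
      stop(sprintf("malformed GenBank %s: unsupported join at line %d",
                   path, lineno))
    }
    a <- as.integer(strsplit(gsub("[<>]", "", segs[1]), "\\.\\.")[[1]])
    b <- as.integer(strsplit(gsub("[<>]", "", segs[2]), "\\.\\.")[[1]])
    return(list(start = a[1], end = b[2], strand = strand, wrap = TRUE))
  }
  xs <- suppressWarnings(
    as.integer(strsplit(gsub("[<>]", "", loc), "\\.\\.")[[1]]))
  if (any(is.na(xs))) {
    stop(sprintf("malformed GenBank %s: bad location '%s' at line %d",
                 path, loc, lineno))
  }
  if (length(xs) == 1) xs <- c(xs, xs)
  list(start = xs[1], end = xs[2], strand = strand, wrap = xs[1] > xs[2])
}

# synonym table: raw annotation spellings -> canonical tokens
gene_synonyms <- function() {
  syn <- list(
    nad1 = c("nd1", "nadh1", "nadh dehydrogenase subunit 1", "mt-nd1"),
    nad2 = c("nd2", "nadh2", "nadh dehydrogenase subunit 2", "mt-nd2"),
    nad3 = c("nd3", "nadh3", "nadh dehydrogenase subunit 3", "mt-nd3"),
    nad4 = c("nd4", "nadh4", "nadh dehydrogenase subunit 4", "mt-nd4"),
    nad4l = c("nd4l", "nadh4l", "nadh dehydrogenase subunit 4l", "mt-nd4l"),
    nad5 = c("nd5", "nadh5", "nadh dehydrogenase subunit 5", "mt-nd5"),
    nad6 = c("nd6", "nadh6", "nadh dehydrogenase subunit 6", "mt-nd6"),
    cox1 = c("coi", "co1", "coxi", "cytochrome c oxidase subunit i",
             "cytochrome c oxidase subunit 1", "mt-co1"),
    cox2 = c("coii", "co2", "coxii", "cytochrome c oxidase subunit ii",
             "cytochrome c oxidase subunit 2", "mt-co2"),
    cox3 = c("coiii", "co3", "coxiii", "cytochrome c oxidase subunit iii",
             "cytochrome c oxidase subunit 3", "mt-co3"),
    atp6 = c("atpase6", "atpase 6", "atp synthase f0 subunit 6", "mt-atp6"),
    atp8 = c("atpase8", "atpase 8", "atp synthase f0 subunit 8", "mt-atp8"),
    cob = c("cytb", "cob", "cyt b", "cytochrome b", "mt-cyb"),
    rrnS = c("12s", "12s rrna", "12s ribosomal rna", "s-rrna", "srrna",
             "small subunit ribosomal rna", "rrn12"),
    rrnL = c("16s", "16s rrna", "16s ribosomal rna", "l-rrna", "lrrna",
             "large subunit ribosomal rna", "rrn16"),
    CR = c("d-loop", "control region", "dloop", "putative control region",
           "cr"),
    OL = c("ol", "origin", "rep_origin", "l-strand origin",
           "origin of l-strand replication",
           "light strand replication origin"))
  syn
}

trna_aa_letter <- function() {
  c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
    Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
    Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
    Tyr = "Y", Val = "V")
}

#' Map an as-annotated feature name onto the controlled vocabulary
#'
#' Resolves the many spellings found in annotations (\code{ND5},
#' \code{NADH5}, \code{COI}/\code{cox1}, \code{12S}/\code{rrnS},
#' \code{D-loop}/\code{CR}, \code{tRNA-Phe}/\code{trnF}, ...) onto the
#' canonical tokens of [mito_vocabulary()]. The two leucine and two serine
#' tRNAs are disambiguated by anticodon when given (standard designation:
#' \code{trnL1}=UAG/CUN, \code{trnL2}=UAA/UUR, \code{trnS1}=GCU/AGY,
#' \code{trnS2}=UGA/UCN), else by positional context (flanking tokens)
#' relative to a reference pattern, else flagged.
#'
#' @param raw_name as-annotated name.
#' @param feature_class one of \code{gene}, \code{tRNA}, \code{rRNA},
#'   \code{D-loop}, \code{origin}, \code{other}.
#' @param anticodon optional anticodon sequence (e.g. \code{"UAG"}).
#' @param context optional character vector of neighboring canonical
#'   tokens, used for L/S disambiguation.
#' @param reference reference [gene_order()] supplying the positional
#'   context of trnL1/trnL2/trnS1/trnS2 (default the vertebrate pattern).
#' @return list with \code{token} (canonical token, \code{"extra"} when
#'   unmappable) and \code{flag} (\code{NA}, \code{"name-unrecognized"} or
#'   \code{"leucine-serine-ambiguous"}).
#' @export
standardize_names <- function(raw_name, feature_class = "gene",
                              anticodon = NULL, context = NULL,
                              reference = NULL) {
  nm <- tolower(trimws(raw_name))
  if (feature_class == "D-loop") return(list(token = "CR", flag = NA_character_))
  if (feature_class == "origin") return(list(token = "OL", flag = NA_character_))
  syn <- gene_synonyms()
  for (tok in names(syn)) {
    if (nm == tolower(tok) || nm %in% syn[[tok]]) {
      return(list(token = tok, flag = NA_character_))
    }
  }
  # tRNA spellings: trnF, trn-F, tRNA-Phe, tRNA Phe, trnL1, trnL(UAG) ...
  aa <- trna_aa_letter()
  m <- regmatches(nm, regexec("^t(?:rna|rn)[- ]?([a-z]{3}|[a-z][12]?)", nm))[[1]]
  paren <- regmatches(nm, regexec("\\(([acgut]{3})\\)", nm))[[1]]
  if (length(paren) == 2 && is.null(anticodon)) anticodon <- toupper(paren[2])
  if (length(m) == 2) {
    code <- m[2]
    letter <- if (nchar(code) == 3) {
      unname(aa[match(code, tolower(names(aa)))])
    } else toupper(substr(code, 1, 1))
    idx <- if (nchar(code) == 2) substr(code, 2, 2) else ""
    if (!is.na(letter) && letter %in% aa) {
      if (!letter %in% c("L", "S")) {
        return(list(token = paste0("trn", letter), flag = NA_character_))
      }
      if (nzchar(idx)) {
        return(list(token = paste0("trn", letter, idx), flag = NA_character_))
      }
      return(disambiguate_ls(letter, anticodon, context, reference))
    }
  }
  list(token = "extra", flag = "name-unrecognized")
}

disambiguate_ls <- function(letter, anticodon, context, reference) {
  if (!is.null(anticodon) && !is.na(anticodon)) {
    ac <- chartr("T", "U", toupper(anticodon))
    tok <- switch(paste0(letter, ":", ac),
                  "L:UAG" = "trnL1", "L:UAA" = "trnL2",
                  "S:GCU" = "trnS1", "S:UGA" = "trnS2",
                  NA_character_)
    if (!is.na(tok)) return(list(token = tok, flag = NA_character_))
  }
  if (!is.null(context) && length(context) > 0) {
    ref <- if (is.null(reference)) vertebrate_order() else reference
    cand <- if (letter == "L") c("trnL1", "trnL2") else c("trnS1", "trnS2")
    hits <- vapply(cand, function(tok) {
      i <- which(ref$token == tok)
      if (length(i) == 0) return(0L)
      n <- length(ref)
      nb <- ref$token[c(if (i == 1) n else i - 1, if (i == n) 1 else i + 1)]
      sum(context %in% nb)
    }, integer(1))
    if (max(hits) > 0 && sum(hits == max(hits)) == 1) {
      return(list(token = cand[which.max(hits)], flag = NA_character_))
    }
  }
  list(token = paste0("trn", letter, "1"), flag = "leucine-serine-ambiguous")
}

#' Detect control regions from intergenic gaps
#'
#' Every unannotated intergenic gap of at least \code{min_gap} bases
#' (default 250 bp) becomes a control-region feature; annotated D-loops
#' pass through unchanged. The circular wrap-around gap between the last
#' and the first feature is included. Overlapping features are tolerated
#' (gap length floors at zero). Raising \code{min_gap} never adds a CR.
#'
#' @param features data.frame as from [parse_features()] (one sample),
#'   sorted by start.
#' @param genome_length total genome length in bp (must be at least the
#'   maximum annotated coordinate).
#' @param min_gap intergenic-length threshold in bp.
#' @return \code{features} with CR rows appended (feature_class
#'   \code{"D-loop"}, raw_name \code{"CR"}), re-sorted by start.
#' @export
detect_control_regions <- function(features, genome_length, min_gap = 250) {
  if (nrow(features) == 0) return(features)
  if (genome_length < max(features$end[!features$wrap])) {
    stop("genome_length smaller than the largest annotated coordinate")
  }
  f <- features[order(features$start), ]
  n <- nrow(f)
  new_rows <- list()
  add_cr <- function(s, e) {
    new_rows[[length(new_rows) + 1L]] <<- data.frame(
      sample_id = f$sample_id[1], raw_name = "CR",
      start = s, end = e, strand = 1L, feature_class = "D-loop",
      anticodon = NA_character_, wrap = s > e,
      length = if (s > e) genome_length - s + 1L + e else e - s + 1L,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n - 1)) {
    gap <- f$start[i + 1] - max(f$end[seq_len(i)][!f$wrap[seq_len(i)]]) - 1L
    if (!is.na(gap) && gap >= min_gap) {
      add_cr(max(f$end[seq_len(i)][!f$wrap[seq_len(i)]]) + 1L,
             f$start[i + 1] - 1L)
    }
  }
  # wrap-around gap: after the last non-wrapping feature back to the first
  if (!any(f$wrap)) {
    gap <- (genome_length - max(f$end)) + (f$start[1] - 1L)
    if (gap >= min_gap) {
      s <- max(f$end) + 1L
      e <- f$start[1] - 1L
      if (s <= genome_length && (e >= 1 || s <= genome_length)) {
        if (f$start[1] == 1L) add_cr(s, genome_length) else add_cr(s, e)
      }
    }
  }
  out <- rbind(f, do.call(rbind, new_rows))
  out[order(out$start), ]
}

#' Build a canonical gene order from parsed features
#'
#' Maps raw names onto canonical tokens (see [standardize_names()]),
#' detects control regions ([detect_control_regions()]) unless already
#' annotated, sorts by position and canonicalizes. Features that cannot be
#' mapped become \code{extra} tokens and are flagged.
#'
#' @param features one sample's features (data.frame).
#' @param genome_length genome length in bp.
#' @param min_gap CR detection threshold; \code{NA} disables detection.
#' @param taxon optional taxon triple.
#' @return list with \code{order} (canonical [gene_order()]) and
#'   \code{flags} (character vector of issue codes collected during
#'   mapping).
#' @export
order_from_features <- function(features, genome_length, min_gap = 250,
                                taxon = NULL) {
  if (!is.na(min_gap)) {
    features <- detect_control_regions(features, genome_length, min_gap)
  }
  f <- features[order(features$start), ]
  flags <- character(0)
  tokens <- character(nrow(f))
  for (i in seq_len(nrow(f))) {
    ctx_idx <- c(if (i > 1) i - 1 else nrow(f), if (i < nrow(f)) i + 1 else 1)
    ctx <- tokens[ctx_idx[ctx_idx < i]]
    res <- standardize_names(f$raw_name[i], f$feature_class[i],
                             anticodon = f$anticodon[i],
                             context = if (length(ctx)) ctx else NULL)
    tokens[i] <- res$token
    if (!is.na(res$flag)) flags <- c(flags, res$flag)
  }
  # second pass for L/S tRNAs once both neighbors are known
  amb <- which(tokens %in% c("trnL1", "trnS1")) # may include flagged guesses
  if ("leucine-serine-ambiguous" %in% flags) {
    for (i in amb) {
      nb <- tokens[c(if (i > 1) i - 1 else nrow(f),
                     if (i < nrow(f)) i + 1 else 1)]
      letter <- substr(tokens[i], 4, 4)
      res <- disambiguate_ls(letter, f$anticodon[i], nb, NULL)
      if (is.na(res$flag)) tokens[i] <- res$token
    }
  }
  signed <- paste0(ifelse(f$strand < 0, "-", ""), tokens)
  go <- canonicalize(gene_order(signed, sample_id = f$sample_id[1],
                                taxon = taxon))
  list(order = go, flags = unique(flags))
}

#' Validate a canonical gene order against a reference pattern
#'
#' Emits the standard error taxonomy for mitogenome annotations:
#' \code{missing-gene} for any of the 37 canonical genes absent;
#' \code{abnormal-strand} for genes whose strand contradicts the reference
#' when the unsigned gene order otherwise matches it exactly (so genuine
#' inversions that also move genes are not falsely flagged);
#' \code{duplicate-unexpected} for tokens with more copies than the
#' reference; \code{name-unrecognized} when \code{extra} tokens are
#' present. Flags supplied via \code{extra_flags} (e.g. from ingest) are
#' merged. A report is always returned; \code{usable} is \code{FALSE} iff
#' \code{missing-gene} or \code{invalid-annotation} is present.
#'
#' @param order canonical [gene_order()].
#' @param reference reference [gene_order()]; default [vertebrate_order()].
#' @param extra_flags additional issue codes to merge.
#' @return list (class \code{validation_report}): \code{sample_id},
#'   \code{issues} (data.frame \code{flag}, \code{detail}), \code{usable}.
#' @export
validate_order <- function(order, reference = vertebrate_order(),
                           extra_flags = character(0)) {
  if (!order$canonical) order <- canonicalize(order)
  issues <- data.frame(flag = character(0), detail = character(0),
                       stringsAsFactors = FALSE)
  add <- function(flag, detail) {
    issues <<- rbind(issues, data.frame(flag = flag, detail = detail,
                                        stringsAsFactors = FALSE))
  }
  missing <- setdiff(mito_required_genes(), order$token)
  for (g in missing) add("missing-gene", g)
  if (identical(order$token, reference$token)) {
    bad <- which(order$strand != reference$strand)
    for (i in bad) add("abnormal-strand", order$token[i])
  }
  qc <- table(order$token); rc <- table(reference$token)
  for (tok in names(qc)) {
    expected <- if (tok %in% names(rc)) rc[[tok]] else 0L
    if (tok != "extra" && qc[[tok]] > expected) {
      add("duplicate-unexpected", tok)
    }
  }
  if ("extra" %in% order$token) add("name-unrecognized", "extra")
  for (fl in extra_flags) add(fl, "")
  usable <- !any(issues$flag %in% c("missing-gene", "invalid-annotation"))
  structure(list(sample_id = order$sample_id, issues = issues,
                 usable = usable),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %s (%d issue%s)\n", x$sample_id,
              if (x$usable) "usable" else "NOT usable", nrow(x$issues),
              if (nrow(x$issues) == 1) "" else "s"))
  if (nrow(x$issues) > 0) print(x$issues)
  invisible(x)
}

#' Write validation reports as CSV
#'
#' @param reports list of \code{validation_report}.
#' @param path file path.
#' @export
write_validation_reports <- function(reports, path) {
  rows <- do.call(rbind, lapply(reports, function(r) {
    if (nrow(r$issues) == 0) {
      data.frame(sample_id = r$sample_id, flag = "", detail = "",
                 usable = r$usable, stringsAsFactors = FALSE)
    } else {
      cbind(sample_id = r$sample_id, r$issues, usable = r$usable)
    }
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
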