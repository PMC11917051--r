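#' Reconcile sample names against a taxonomy checklist
#'
#' Emulates an offline checklist reconciliation: sample organism names
#' (NCBI-style binomials, possibly with qualifiers) are cleaned, routed
#' and matched against an authoritative checklist of accepted genera with
#' per-genus species counts.
#'
#' Routing rules: names containing \code{"cf."} or \code{"sp."} go to the
#' unidentified list; hybrids (\code{" x "} or a multiplication sign) are
#' flagged and excluded; an \code{"aff."} qualifier is dropped and the
#' name matched; trinomials (subspecies) are truncated to the binomial.
#' Cleaned binomials are deduplicated and exact-matched against the
#' checklist by genus; the optional \code{manual_map} (columns
#' \code{raw_name}, \code{family}, \code{genus}, \code{species}) resolves
#' the remainder. Names still unmatched are listed as unresolved, not
#' fatal.
#'
#' Coverage is reported per rank against the checklist totals: covered
#' families / checklist families, covered genera / checklist genera,
#' matched species / checklist species-count sum. Per-genus species
#' coverage (sampled species / checklist count) is summarized by mean and
#' median. Percentages are invariant to sample duplication.
#'
#' @param samples data.frame with columns \code{sample_id},
#'   \code{organism}.
#' @param checklist data.frame with columns \code{family}, \code{genus},
#'   \code{species_count} ((family, genus) unique, counts >= 0).
#' @param manual_map optional manual mapping table (see above).
#' @return list of class \code{taxonomy_reconciliation}:
#'   \code{table} (per-sample: sample_id, organism, binomial, family,
#'   genus, species, status), \code{coverage} (rank, covered, total, pct),
#'   \code{per_genus} (genus, family, sampled, species_count, pct) with
#'   mean/median in attributes, \code{unidentified}, \code{hybrids},
#'   \code{unresolved}.
#' @export
reconcile_taxonomy <- function(samples, checklist, manual_map = NULL) {
  if (anyDuplicated(paste(checklist$family, checklist$genus))) {
    stop("checklist (family, genus) pairs must be unique")
  }
  org <- trimws(samples$organism)
  status <- rep("matched", nrow(samples))
  is_unident <- grepl("\\bcf\\.|\\bsp\\.", org)
  is_hybrid <- grepl(" x |×", org)
  status[is_unident] <- "unidentified"
  status[is_hybrid] <- "hybrid"
  clean <- sub("\\baff\\.\\s*", "", org)          # drop 'aff.' qualifier
  clean <- gsub("\\s+", " ", clean)
  words <- strsplit(clean, " ")
  binomial <- vapply(words, function(w) {
    if (length(w) >= 2) paste(w[1], w[2]) else w[1]
  }, character(1))
  binomial[is_unident | is_hybrid] <- NA_character_
  genus <- vapply(strsplit(binomial, " "), `[`, character(1), 1)
  hit <- match(genus, checklist$genus)
  family <- checklist$family[hit]
  species <- binomial
  status[!is.na(binomial) & is.na(hit)] <- "unresolved"
  if (!is.null(manual_map) && nrow(manual_map) > 0) {
    um <- which(status == "unresolved")
    mm <- match(org[um], manual_map$raw_name)
    ok <- !is.na(mm)
    family[um[ok]] <- manual_map$family[mm[ok]]
    genus[um[ok]] <- manual_map$genus[mm[ok]]
    species[um[ok]] <- manual_map$species[mm[ok]]
    status[um[ok]] <- "manual"
  }
  tab <- data.frame(sample_id = samples$sample_id, organism = org,
                    binomial = binomial, family = family, genus = genus,
                    species = species, status = status,
                    stringsAsFactors = FALSE)
  ok <- tab$status %in% c("matched", "manual")
  cov_fam <- length(unique(tab$family[ok]))
  cov_gen <- length(unique(tab$genus[ok]))
  cov_sp <- length(unique(tab$species[ok]))
  tot_fam <- length(unique(checklist$family))
  tot_gen <- nrow(checklist)
  tot_sp <- sum(checklist$species_count)
  coverage <- data.frame(
    rank = c("family", "genus", "species"),
    covered = c(cov_fam, cov_gen, cov_sp),
    total = c(tot_fam, tot_gen, tot_sp),
    pct = round(100 * c(cov_fam / tot_fam, cov_gen / tot_gen,
                        cov_sp / tot_sp), 2),
    stringsAsFactors = FALSE)
  sampled <- tab[ok, c("genus", "species")]
  sampled <- unique(sampled)
  cnt <- table(sampled$genus)
  gidx <- match(names(cnt), checklist$genus)
  per_genus <- data.frame(
    genus = names(cnt),
    family = checklist$family[gidx],
    sampled = as.integer(cnt),
    species_count = checklist$species_count[gidx],
    stringsAsFactors = FALSE)
  per_genus$pct <- ifelse(per_genus$species_count > 0,
                          100 * pmin(1, per_genus$sampled /
                                        per_genus$species_count), NA)
  per_genus <- per_genus[!is.na(per_genus$species_count), ]
  attr(per_genus, "mean_pct") <- mean(per_genus$pct, na.rm = TRUE)
  attr(per_genus, "median_pct") <- stats::median(per_genus$pct, na.rm = TRUE)
  structure(
    list(table = tab, coverage = coverage, per_genus = per_genus,
         unidentified = tab$organism[tab$status == "unidentified"],
         hybrids = tab$organism[tab$status == "hybrid"],
         unresolved = unique(tab$organism[tab$status == "unresolved"])),
    class = "taxonomy_reconciliation")
}

#' @export
print.taxonomy_reconciliation <- function(x, ...) {
  cat("<taxonomy_reconciliation>\n")
  print(x$coverage)
  cat(sprintf("per-genus species coverage: mean %.1f%%, median %.1f%%\n",
              attr(x$per_genus, "mean_pct"), attr(x$per_genus, "median_pct")))
  cat(sprintf("unidentified %d, hybrids %d, unresolved %d\n",
              length(x$unidentified), length(x$hybrids),
              length(x$unresolved)))
  invisible(x)
}

#' Read and write taxonomy checklist CSV
#'
#' Columns \code{family}, \code{genus}, \code{species_count}.
#'
#' @param path file path.
#' @export
read_checklist <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_checklist
#' @param checklist data.frame.
#' @export
write_checklist <- function(checklist, path) {
  utils::write.csv(checklist, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_checklist
#' @param recon a \code{taxonomy_reconciliation}.
#' @export
write_reconciled_samples <- function(recon, path) {
  utils::write.csv(recon$table, path, row.names = FALSE)
  invisible(path)
}
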