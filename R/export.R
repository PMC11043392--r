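# Writers for standard genetics formats: FASTA, Newick, NEXUS, VCF.
# The NEXUS export targets external coalescent (skyline) inference: an
# alignment of the sampled haplotypes plus the gene tree, for a sample of
# 10 males and 10 females per village at the final generation.

#' Write haplotypes as FASTA
#'
#' Writes the segregating-site haplotypes of a [drop_mutations()] result (an
#' alignment of the variable positions; invariant sites are omitted).
#'
#' @param seqs a `sequence_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(inherits(seqs, "sequence_set"))
  m <- as.matrix(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    writeLines(c(paste0(">", rownames(m)[i]),
                 paste(m[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Write a gene tree as Newick
#'
#' @param tree a `gene_tree`.
#' @param path output file.
#' @param units `"generations"` (default) or `"years"` (scaled by
#'   `generation_time`).
#' @param generation_time years per generation.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, units = c("generations", "years"),
                         generation_time = 25) {
  units <- match.arg(units)
  phy <- as.phylo.gene_tree(tree, generation_time =
                              if (units == "years") generation_time else NULL)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write a NEXUS file with alignment and tree
#'
#' @param seqs a `sequence_set`.
#' @param tree the matching `gene_tree` (same tips), or NULL to omit the
#'   trees block.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nexus_sample <- function(seqs, tree = NULL, path) {
  stopifnot(inherits(seqs, "sequence_set"))
  m <- as.matrix(seqs)
  labels <- rownames(m)
  ntax <- nrow(m)
  nchar <- ncol(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines(c("BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", ntax, max(nchar, 1L)),
               "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
               "  MATRIX"), con)
  if (nchar == 0L) {
    # degenerate: no segregating site; emit a one-column constant alignment
    for (i in seq_len(ntax)) writeLines(sprintf("  %s A", labels[i]), con)
  } else {
    for (i in seq_len(ntax)) {
      writeLines(sprintf("  %s %s", labels[i], paste(m[i, ], collapse = "")),
                 con)
    }
  }
  writeLines(c("  ;", "END;"), con)
  if (!is.null(tree)) {
    phy <- as.phylo.gene_tree(tree)
    writeLines(c("BEGIN TREES;",
                 paste0("  TREE genealogy = ",
                        ape::write.tree(phy)),
                 "END;"), con)
  }
  invisible(path)
}

#' Write haploid genotypes as VCF
#'
#' One row per segregating site, 1-based positions, haploid GT field
#' (0 = ancestral, 1 = derived).
#'
#' @param seqs a `sequence_set`.
#' @param path output file.
#' @param chrom contig name (defaults to the marker name).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(seqs, path, chrom = NULL) {
  stopifnot(inherits(seqs, "sequence_set"))
  if (is.null(chrom)) chrom <- if (seqs$marker == "Y") "Y" else "MT"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=patriseg",
               sprintf("##contig=<ID=%s,length=%d>", chrom,
                       as.integer(seqs$L)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  samples <- make.unique(paste0("ind_", seqs$labels))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  S <- length(seqs$positions)
  if (S > 0L) {
    gt <- matrix("0", nrow = S, ncol = seqs$n_tips)
    for (j in seq_len(S)) gt[j, seqs$carriers[[j]]] <- "1"
    rows <- vapply(seq_len(S), function(j) {
      paste(c(chrom, seqs$positions[j], ".", seqs$ancestral[j],
              seqs$derived[j], ".", "PASS", ".", "GT", gt[j, ]),
            collapse = "\t")
    }, "")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Export a sampled genealogy and haplotypes in standard formats
#'
#' Draws the external-inference sample from the final generation of a run
#' kept with `keep_state = TRUE`: `males_per_village` males and
#' `females_per_village` females per village (10 + 10 by default, i.e. 100
#' individuals). The Y genealogy and haplotypes cover the sampled males, the
#' mtDNA genealogy and haplotypes the full sample (mtDNA is carried by both
#' sexes). Files are written per marker as
#' `<prefix>_<marker>.<fasta|nwk|nex|vcf>`.
#'
#' @param run a `patriseg_run` created with `keep_state = TRUE`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param formats subset of `c("fasta", "newick", "nexus", "vcf")`.
#' @param males_per_village,females_per_village sample composition.
#' @param units branch-length units for the Newick export.
#' @return named list of written file paths, invisibly.
#' @export
export_sample <- function(run, dir, prefix = run$scenario,
                          formats = c("fasta", "newick", "nexus", "vcf"),
                          males_per_village = 10L, females_per_village = 10L,
                          units = "generations") {
  stopifnot(inherits(run, "patriseg_run"))
  if (is.null(run$state)) {
    stop("run was not kept: call simulate_replicate(..., keep_state = TRUE)",
         call. = FALSE)
  }
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pop <- run$state
  cfg <- run$config
  t <- pop$generation
  sample_v <- function(v, sexcode, k) {
    idx <- which(pop$village == v & pop$sex == sexcode)
    if (length(idx) > k) idx <- idx[sample.int(length(idx), k)]
    pop$id[idx]
  }
  males <- unlist(lapply(seq_len(pop$n_villages), sample_v, 1L,
                         males_per_village))
  females <- unlist(lapply(seq_len(pop$n_villages), sample_v, 2L,
                           females_per_village))
  marker_sets <- list(
    Y = list(ids = males, burn = run$burn_in$Y,
             tips = run$founder_tips$Y, mu = cfg$mu_Y, L = cfg$len_Y),
    mtDNA = list(ids = c(males, females), burn = run$burn_in$mtDNA,
                 tips = run$founder_tips$mtDNA, mu = cfg$mu_mt,
                 L = cfg$len_mt))
  paths <- list()
  for (marker in names(marker_sets)) {
    s <- marker_sets[[marker]]
    tree <- extract_gene_tree(s$ids, run$ped, s$burn, s$tips, t, marker)
    seqs <- drop_mutations(tree, s$mu, s$L)
    base <- file.path(dir, paste0(prefix, "_", marker))
    if ("fasta" %in% formats) {
      paths[[paste0(marker, "_fasta")]] <-
        write_fasta(seqs, paste0(base, ".fasta"))
    }
    if ("newick" %in% formats) {
      paths[[paste0(marker, "_newick")]] <-
        write_newick(tree, paste0(base, ".nwk"), units = units,
                     generation_time = cfg$generation_time)
    }
    if ("nexus" %in% formats) {
      paths[[paste0(marker, "_nexus")]] <-
        write_nexus_sample(seqs, tree, paste0(base, ".nex"))
    }
    if ("vcf" %in% formats) {
      paths[[paste0(marker, "_vcf")]] <-
        write_vcf(seqs, paste0(base, ".vcf"))
    }
  }
  invisible(paths)
}
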