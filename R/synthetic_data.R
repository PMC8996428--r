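# Seeded generator of a toy hexaploid genome with planted, manifest-backed
# features: VQ genes in homoeolog groups of controlled A:B:D ratios,
# duplication pairs with exact synonymous/nonsynonymous codon changes,
# SSRs and promoter cis-elements planted into rejection-sampled clean
# background, and simulated TPM / qRT-PCR tables. Every planted feature is
# recorded in a ground-truth manifest sufficient to verify pipeline output.

#' Generator configuration
#'
#' Defaults reproduce the family structure of the hexaploid wheat VQ
#' survey: 113 genes in 40 homoeolog groups (triads 25 groups/75 genes,
#' homoeolog-specific duplications 4/17, single-homoeolog losses 8/16,
#' one other-ratio group of counts (0,2,1), 2 orphans), 103/113 intronless
#' genes, the observed motif-variant census (LTG 86, FTG 11, ITG 3, VTG 8,
#' VH-core VTG 4, VMA 1), 28 SSRs in 25 genes (21 tri / 2 di / 5 mono),
#' 5 duplication pairs and a W-box planted in 55 of 113 promoters.
#'
#' @param seed Integer seed; the whole generation is deterministic given it.
#' @param n_chromosome_groups Homoeologous chromosome groups (default 7).
#' @param subgenomes Subgenome letters (default A, B, D).
#' @param ratio_census List of per-category member-count patterns; see
#'   defaults.
#' @param motif_variant_census Named counts per motif variant; names
#'   `LTG`, `FTG`, `ITG`, `VTG`, `VTG_VH` (VH core), `VMA`; must sum to
#'   the gene total.
#' @param intronless_count Number of single-exon genes.
#' @param protein_length Range of founder protein lengths (residues).
#' @param utr_length 3' UTR length (bp), the planting ground for SSRs.
#' @param intron_length Intron length (bp) for two-exon genes.
#' @param spacer_length Intergenic spacer (bp).
#' @param promoter_length Promoter length (bp) used for planting.
#' @param duplication_pairs List of `list(syn=, nonsyn=, kind=)` entries;
#'   `kind` is `"tandem"` or `"segmental"`.
#' @param ssr_plan List: `n_mono`, `n_di`, `n_tri`, `n_genes`,
#'   `n_two_ssr_genes`, `n_compound_genes`.
#' @param cis_plan Named integer vector: planted element -> number of
#'   promoters carrying exactly one occurrence.
#' @param expression List: `n_expressed_groups`, `tpm_range`,
#'   `columns` (named character vector column -> organ class).
#' @param qpcr List: `n_genes`, `conditions`, `timepoints`, `replicates`,
#'   `ct_noise_sd`, `strong_fold_log2`.
#' @return Config list of class `survey_config`.
#' @export
survey_config <- function(
    seed = 42L,
    n_chromosome_groups = 7L,
    subgenomes = c("A", "B", "D"),
    ratio_census = list(
      TRIAD_1_1_1 = replicate(25, c(1, 1, 1), simplify = FALSE),
      DUP_n_1_1 = list(c(3, 1, 1), c(2, 1, 1), c(2, 1, 1), c(2, 1, 1)),
      LOSS_1_1_0 = rep(list(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)), length.out = 8),
      OTHER = list(c(0, 2, 1)),
      ORPHAN = list(c(1, 0, 0), c(0, 0, 1))),
    motif_variant_census = c(LTG = 86, FTG = 11, ITG = 3, VTG = 8,
                             VTG_VH = 4, VMA = 1),
    intronless_count = 103L,
    protein_length = c(120L, 240L),
    utr_length = 220L,
    intron_length = 150L,
    spacer_length = 200L,
    promoter_length = 1500L,
    duplication_pairs = list(
      list(syn = 6L, nonsyn = 0L, kind = "tandem"),
      list(syn = 2L, nonsyn = 3L, kind = "tandem"),
      list(syn = 8L, nonsyn = 1L, kind = "segmental"),
      list(syn = 0L, nonsyn = 4L, kind = "segmental"),
      list(syn = 5L, nonsyn = 5L, kind = "segmental")),
    ssr_plan = list(n_mono = 5L, n_di = 2L, n_tri = 21L,
                    n_genes = 25L, n_two_ssr_genes = 3L,
                    n_compound_genes = 2L),
    cis_plan = c(`W-box` = 55L, `CGTCA-motif` = 100L, ABRE = 98L,
                 MBS = 60L, `RY-element` = 30L),
    expression = list(
      n_expressed_groups = 30L,
      tpm_range = c(1.5, 55),
      columns = c(leaf_1 = "leaf_stem", leaf_2 = "leaf_stem",
                  stem_1 = "leaf_stem", stem_2 = "leaf_stem",
                  root_1 = "root", root_2 = "root", root_3 = "root",
                  spike_1 = "spike", spike_2 = "spike", spike_3 = "spike",
                  grain_1 = "grain", grain_2 = "grain", grain_3 = "grain")),
    qpcr = list(n_genes = 12L,
                conditions = c("PEG", "NaCl", "HT", "LT", "MeJA", "SA", "ABA"),
                timepoints = c(0, 1, 3, 6, 12, 24, 48),
                replicates = 3L, ct_noise_sd = 0.1,
                strong_fold_log2 = 4)) {
  cfg <- list(seed = seed, n_chromosome_groups = n_chromosome_groups,
              subgenomes = subgenomes, ratio_census = ratio_census,
              motif_variant_census = motif_variant_census,
              intronless_count = intronless_count,
              protein_length = protein_length, utr_length = utr_length,
              intron_length = intron_length, spacer_length = spacer_length,
              promoter_length = promoter_length,
              duplication_pairs = duplication_pairs, ssr_plan = ssr_plan,
              cis_plan = cis_plan, expression = expression, qpcr = qpcr)
  n_genes <- sum(unlist(lapply(unlist(ratio_census, recursive = FALSE), sum)))
  if (sum(motif_variant_census) != n_genes)
    stop("motif variant census must sum to the gene total (", n_genes, ")")
  if (intronless_count > n_genes) stop("intronless_count exceeds gene total")
  if (ssr_plan$n_mono + ssr_plan$n_di + ssr_plan$n_tri !=
      ssr_plan$n_genes + ssr_plan$n_two_ssr_genes)
    stop("ssr plan inconsistent: class counts must equal planting slots")
  if (ssr_plan$n_compound_genes > ssr_plan$n_two_ssr_genes)
    stop("ssr plan inconsistent: compound genes exceed two-SSR genes")
  if (any(cis_plan > n_genes)) stop("cis plantings exceed gene count")
  structure(cfg, class = "survey_config")
}

# ---- low-level random-sequence helpers -------------------------------------

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Re-randomize any window matching one of the patterns until the sequence is
# clean (rejection sampling of background windows keeps composition uniform).
clean_dna <- function(n, patterns, max_iter = 200L) {
  s <- rand_dna(n)
  if (length(patterns) == 0L) return(s)
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE
    for (pat in patterns) {
      pos <- match_positions(s, pat)
      if (length(pos) > 0L) {
        dirty <- TRUE
        for (p in pos) {
          w <- nchar(pat)
          substr(s, p, p + w - 1L) <- rand_dna(w)
        }
      }
    }
    if (!dirty) return(s)
  }
  stop("clean_dna failed to converge")
}

# Background DNA free of threshold-passing SSRs (checked post hoc).
clean_dna_no_ssr <- function(n, patterns = character(0),
                             thresholds = MISA_THRESHOLDS, max_iter = 60L) {
  for (iter in seq_len(max_iter)) {
    s <- clean_dna(n, patterns)
    if (nrow(find_ssrs(s, thresholds)) == 0L) return(s)
  }
  stop("clean_dna_no_ssr failed to converge")
}

vq_prefix_regex <- function(hydrophobic_set = HYDROPHOBIC_DEFAULT)
  paste0("F.{3}V[QH].[", paste(hydrophobic_set, collapse = ""), "]")

# Random protein with no window matching the VQ 8-position prefix.
clean_protein <- function(n, max_iter = 200L) {
  re <- vq_prefix_regex()
  for (iter in seq_len(max_iter)) {
    s <- paste(sample(AA20, n, replace = TRUE), collapse = "")
    if (!grepl(re, s, perl = TRUE)) return(s)
  }
  stop("clean_protein failed to converge")
}

make_motif_decamer <- function(variant) {
  # variant is one of LTG/FTG/ITG/VTG (VQ core), VTG_VH (VH core), VMA
  core <- if (variant == "VTG_VH") "H" else "Q"
  term <- switch(variant, VTG_VH = "VTG", VMA = "VMA", variant)
  xs <- sample(setdiff(AA20, "F"), 3L, replace = TRUE)
  x7 <- sample(setdiff(AA20, "F"), 1L)
  paste0("F", paste(xs, collapse = ""), "V", core, x7, term)
}

CODONS_BY_AA <- local({
  sense <- GENETIC_CODE_STD[GENETIC_CODE_STD != "*"]
  split(names(sense), sense)
})

reverse_translate <- function(protein, stop_codon = "TGA") {
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- CODONS_BY_AA[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""), stop_codon)
}

# single-nucleotide neighbors of a codon, split by substitution class
codon_neighbors <- function(codon) {
  nt <- c("T", "C", "A", "G")
  syn <- character(0); nonsyn <- character(0)
  for (pos in 1:3) {
    for (alt in setdiff(nt, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      if (mut %in% STOP_CODONS) next
      if (GENETIC_CODE_STD[[mut]] == GENETIC_CODE_STD[[codon]])
        syn <- c(syn, mut) else nonsyn <- c(nonsyn, mut)
    }
  }
  list(syn = syn, nonsyn = nonsyn)
}

# Apply exactly (syn, nonsyn) single-codon changes to a CDS, avoiding the
# motif codons, the initiator and the stop, one change per codon.
mutate_cds <- function(cds, syn, nonsyn, motif_codon_range, max_iter = 100L) {
  codons <- split_codons(cds)
  n <- length(codons)
  forbidden <- c(1L, n, motif_codon_range)
  for (iter in seq_len(max_iter)) {
    cand <- setdiff(seq_len(n), forbidden)
    cand <- cand[sample.int(length(cand))]
    new_codons <- codons
    done_syn <- 0L; done_nonsyn <- 0L
    for (idx in cand) {
      if (done_syn == syn && done_nonsyn == nonsyn) break
      nb <- codon_neighbors(codons[idx])
      if (done_syn < syn && length(nb$syn) > 0L) {
        new_codons[idx] <- nb$syn[sample.int(length(nb$syn), 1L)]
        done_syn <- done_syn + 1L
      } else if (done_nonsyn < nonsyn && length(nb$nonsyn) > 0L) {
        new_codons[idx] <- nb$nonsyn[sample.int(length(nb$nonsyn), 1L)]
        done_nonsyn <- done_nonsyn + 1L
      }
    }
    if (done_syn == syn && done_nonsyn == nonsyn)
      return(paste(new_codons, collapse = ""))
  }
  stop("mutate_cds: could not place requested substitutions")
}

# ---- the generator ---------------------------------------------------------

#' Generate a synthetic hexaploid survey fixture
#'
#' Writes genome FASTA, GFF3 annotation, CDS and protein FASTA, group
#' membership TSV, TPM and qPCR TSV tables plus a JSON ground-truth
#' manifest to `out_dir`. Deterministic given `config$seed`.
#'
#' @param config A [survey_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
generate_survey_data <- function(config = survey_config(), out_dir) {
  stopifnot(inherits(config, "survey_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  subg <- config$subgenomes
  chrom_names <- as.vector(t(outer(seq_len(config$n_chromosome_groups), subg,
                                   paste0)))

  ## 1. group scaffold -------------------------------------------------------
  groups <- list(); gi <- 0L
  for (cat in names(config$ratio_census)) {
    for (pattern in config$ratio_census[[cat]]) {
      gi <- gi + 1L
      groups[[gi]] <- list(group_id = sprintf("G%02d", gi), category = cat,
                           counts = stats::setNames(pattern, subg),
                           chrom_group = ((gi - 1L) %% config$n_chromosome_groups) + 1L)
    }
  }
  genes <- list()
  for (g in groups) {
    for (sgi in seq_along(subg)) {
      for (copy in seq_len(g$counts[[sgi]])) {
        genes[[length(genes) + 1L]] <- list(
          gene_id = sprintf("VQg%03d", length(genes) + 1L),
          group_id = g$group_id, category = g$category,
          chromosome = paste0(g$chrom_group, subg[sgi]),
          subgenome = subg[sgi], copy = copy)
      }
    }
  }
  n_genes <- length(genes)
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  gene_ids <- names(genes)

  ## 2. duplication pairs ----------------------------------------------------
  dup_groups <- vapply(groups, function(g) g$category == "DUP_n_1_1", logical(1))
  tandem_sources <- list(); seg_used <- character(0)
  pairs <- list()
  dup_group_ids <- vapply(groups[dup_groups], `[[`, character(1), "group_id")
  tandem_wanted <- sum(vapply(config$duplication_pairs, function(p)
    p$kind == "tandem", logical(1)))
  seg_wanted <- length(config$duplication_pairs) - tandem_wanted
  # tandem pairs: copy-1 and copy-2 inparalogs of a DUP group (same chromosome)
  ti <- 0L
  for (gid in dup_group_ids) {
    if (ti >= tandem_wanted) break
    members <- gene_ids[vapply(genes, function(x)
      x$group_id == gid && x$copy <= 2L &&
        sum(vapply(genes, function(y)
          y$group_id == gid && y$subgenome == x$subgenome, logical(1))) >= 2L,
      logical(1))]
    if (length(members) < 2L) next
    ti <- ti + 1L
    pairs[[length(pairs) + 1L]] <- list(a = members[1L], b = members[2L],
                                        kind = "tandem")
  }
  # segmental pairs: cross-chromosome copies between loss-group members
  loss_members <- gene_ids[vapply(genes, function(x)
    x$category == "LOSS_1_1_0", logical(1))]
  si <- 0L; li <- 1L
  while (si < seg_wanted && li + 1L <= length(loss_members)) {
    a <- loss_members[li]; b <- loss_members[li + 1L]
    li <- li + 2L
    if (genes[[a]]$chromosome == genes[[b]]$chromosome) next
    si <- si + 1L
    pairs[[length(pairs) + 1L]] <- list(a = a, b = b, kind = "segmental")
  }
  if (length(pairs) != length(config$duplication_pairs))
    stop("could not realize the configured duplication pairs")
  for (k in seq_along(pairs)) {
    pairs[[k]]$syn <- config$duplication_pairs[[k]]$syn
    pairs[[k]]$nonsyn <- config$duplication_pairs[[k]]$nonsyn
    if (pairs[[k]]$kind != config$duplication_pairs[[k]]$kind)
      stop("pair kind mismatch in generator plan")
  }
  copy_of <- stats::setNames(vapply(pairs, `[[`, character(1), "a"),
                             vapply(pairs, `[[`, character(1), "b"))

  ## 3. motif variants ---------------------------------------------------------
  variant_pool <- rep(names(config$motif_variant_census),
                      times = config$motif_variant_census)
  variants <- stats::setNames(rep(NA_character_, n_genes), gene_ids)
  # copies inherit the source variant; assign sources first from the pool
  pool <- sample(variant_pool)
  for (b in names(copy_of)) variants[b] <- ""   # placeholder, set below
  free <- setdiff(gene_ids, names(copy_of))
  # draw source variants such that source+copy pairs drain matching labels
  sources <- unique(unname(copy_of))
  for (s in sources) {
    # need a label with >= 2 remaining (source + its copies)
    n_need <- 1L + sum(copy_of == s)
    tab <- table(pool)
    ok <- names(tab)[tab >= n_need]
    lab <- ok[sample.int(length(ok), 1L)]
    variants[s] <- lab
    for (b in names(copy_of)[copy_of == s]) variants[b] <- lab
    for (dropped in seq_len(n_need)) pool <- pool[-match(lab, pool)]
  }
  rest <- setdiff(free, sources)
  variants[rest] <- pool[seq_along(rest)]

  ## 4. founder proteins and CDS ----------------------------------------------
  plen <- config$protein_length
  re8 <- vq_prefix_regex()
  proteins <- character(0); cds <- character(0)
  motif_offset <- stats::setNames(integer(n_genes), gene_ids)
  build_protein <- function(variant) {
    for (iter in 1:100) {
      L <- sample(plen[1]:plen[2], 1L)
      body <- clean_protein(L - 1L)
      off <- sample(10:(L - 15L), 1L)  # 1-based position of F, after the M
      dec <- make_motif_decamer(variant)
      prot <- paste0("M", substr(body, 1L, off - 2L), dec,
                     substr(body, off + 9L, L - 1L))
      m <- gregexpr(re8, prot, perl = TRUE)[[1]]
      if (length(m) == 1L && m[1L] == off) return(list(prot = prot, off = off))
    }
    stop("could not build a clean motif-bearing protein")
  }
  build_cds <- function(prot, max_iter = 50L) {
    for (iter in seq_len(max_iter)) {
      s <- reverse_translate(prot, stop_codon = sample(STOP_CODONS, 1L))
      if (nrow(find_ssrs(s)) == 0L) return(s)
    }
    stop("could not build an SSR-free CDS")
  }
  for (id in setdiff(gene_ids, names(copy_of))) {
    bp <- build_protein(variants[id])
    proteins[id] <- bp$prot
    motif_offset[id] <- bp$off - 1L   # 0-based F offset
    cds[id] <- build_cds(bp$prot)
  }
  # mutated copies
  for (b in names(copy_of)) {
    a <- copy_of[[b]]
    k <- which(vapply(pairs, function(p) p$b == b, logical(1)))
    p <- pairs[[k]]
    motif_range <- (motif_offset[a] + 1L):(motif_offset[a] + 10L)
    for (iter in 1:50) {
      mut <- mutate_cds(cds[a], p$syn, p$nonsyn, motif_range)
      prot <- translate_cds(mut)
      m <- gregexpr(re8, prot, perl = TRUE)[[1]]
      if (length(m) == 1L && m[1L] == motif_offset[a] + 1L &&
          nrow(find_ssrs(mut)) == 0L) {
        cds[b] <- mut
        proteins[b] <- prot
        motif_offset[b] <- motif_offset[a]
        break
      }
      if (iter == 50L) stop("could not build mutated copy for ", b)
    }
  }

  ## 5. gene structure: introns, UTRs, SSR planting ---------------------------
  n_intron_genes <- n_genes - config$intronless_count
  intron_genes <- sample(gene_ids, n_intron_genes)
  ssr_plan <- config$ssr_plan
  ssr_genes <- sample(setdiff(gene_ids, character(0)), ssr_plan$n_genes)
  two_ssr <- sample(ssr_genes, ssr_plan$n_two_ssr_genes)
  compound_genes <- two_ssr[seq_len(ssr_plan$n_compound_genes)]
  ssr_units <- list(
    mono = c("A", "T", "G", "C"),
    di = c("AG", "CT", "TA", "GA"),
    tri = c("AGC", "CTT", "AAG", "TGA", "GAT", "CAG"))
  ssr_counts <- list(mono = 10:12, di = 6:8, tri = 5:7)
  ssr_class_pool <- sample(c(rep("mono", ssr_plan$n_mono),
                             rep("di", ssr_plan$n_di),
                             rep("tri", ssr_plan$n_tri)))
  # assign classes to slots: each ssr gene one slot, two-SSR genes a second
  slot_genes <- c(ssr_genes, two_ssr)
  ssr_truth <- list()
  utr_seqs <- stats::setNames(character(n_genes), gene_ids)
  utr_len <- config$utr_length
  build_utr <- function(plants, compound, max_iter = 80L) {
    # plants: list of (unit, count); returns list(seq, starts)
    for (iter in seq_len(max_iter)) {
      s <- clean_dna_no_ssr(utr_len)
      starts <- integer(0)
      if (length(plants) > 0L) {
        lens <- vapply(plants, function(p) nchar(p$unit) * p$count, integer(1))
        if (length(plants) == 1L) {
          starts <- sample(10:(utr_len - lens[1L] - 10L), 1L)
        } else {
          gap <- if (compound) sample(20:80, 1L) else 110L
          total <- lens[1L] + gap + lens[2L]
          if (total + 20L > utr_len) next
          s1 <- sample(5:(utr_len - total - 5L), 1L)
          starts <- c(s1, s1 + lens[1L] + gap)
        }
        for (k in seq_along(plants)) {
          rep_seq <- strrep(plants[[k]]$unit, plants[[k]]$count)
          substr(s, starts[k], starts[k] + nchar(rep_seq) - 1L) <- rep_seq
        }
      }
      found <- find_ssrs(s)
      want_n <- length(plants)
      if (nrow(found) == want_n &&
          (want_n == 0L ||
           (all(found$start == sort(starts)) &&
            all(found$repeat_count == vapply(plants, `[[`, integer(1), "count")[order(starts)]))))
        return(list(seq = s, starts = starts))
    }
    stop("build_utr failed")
  }
  slot_idx <- 0L
  gene_plants <- stats::setNames(vector("list", n_genes), gene_ids)
  for (sg in slot_genes) {
    slot_idx <- slot_idx + 1L
    cls <- ssr_class_pool[slot_idx]
    unit <- sample(ssr_units[[cls]], 1L)
    count <- sample(ssr_counts[[cls]], 1L)
    gene_plants[[sg]] <- c(gene_plants[[sg]],
                           list(list(unit = unit, count = as.integer(count))))
  }
  for (id in gene_ids) {
    plants <- gene_plants[[id]]
    u <- build_utr(plants, compound = id %in% compound_genes)
    utr_seqs[id] <- u$seq
    if (length(plants) > 0L) {
      for (k in seq_along(plants)) {
        ssr_truth[[length(ssr_truth) + 1L]] <- data.frame(
          gene_id = id, motif = plants[[k]]$unit,
          repeat_count = plants[[k]]$count,
          utr_start = u$starts[k],
          compound = id %in% compound_genes,
          stringsAsFactors = FALSE)
      }
    }
  }
  ssr_truth <- do.call(rbind, ssr_truth)

  ## 6. promoters with planted cis-elements -----------------------------------
  catalog <- default_cis_catalog()
  planted_elements <- names(config$cis_plan)
  plant_patterns <- unlist(lapply(planted_elements, function(el)
    catalog$entries[[el]]))
  clean_pats <- unique(c(plant_patterns,
                         vapply(plant_patterns, revcomp_iupac, character(1))))
  carriers <- lapply(config$cis_plan, function(n) sample(gene_ids, n))
  prom_len <- config$promoter_length
  promoters <- stats::setNames(character(n_genes), gene_ids)
  cis_truth <- list()
  for (id in gene_ids) {
    mine <- planted_elements[vapply(planted_elements, function(el)
      id %in% carriers[[el]], logical(1))]
    for (iter in 1:60) {
      s <- clean_dna(prom_len, clean_pats)
      offs <- integer(0); pats <- character(0)
      ok <- TRUE
      used <- IRanges::IRanges()
      for (el in mine) {
        pat <- sample(catalog$entries[[el]], 1L)
        w <- nchar(pat)
        for (try in 1:50) {
          o <- sample(1:(prom_len - w + 1L), 1L)
          cand <- IRanges::IRanges(o - w, o + 2L * w)  # keep plantings apart
          if (length(used) == 0L ||
              sum(IRanges::countOverlaps(cand, used)) == 0L) break
          o <- NA_integer_
        }
        if (is.na(o)) { ok <- FALSE; break }
        used <- c(used, IRanges::IRanges(o - w, o + 2L * w))
        substr(s, o, o + w - 1L) <- pat
        offs <- c(offs, o); pats <- c(pats, el)
      }
      if (!ok) next
      # verify: each planted pattern occurs exactly once, clean otherwise
      counts_ok <- all(vapply(seq_along(plant_patterns), function(pi) {
        pat <- plant_patterns[pi]
        el_of <- planted_elements[vapply(planted_elements, function(el)
          pat %in% catalog$entries[[el]], logical(1))][1L]
        n_plant <- sum(pats == el_of &
                         vapply(offs, function(o)
                           substr(s, o, o + nchar(pat) - 1L) == pat, logical(1)))
        length(match_positions(s, pat)) == n_plant &&
          length(match_positions(s, revcomp_iupac(pat))) == 0L
      }, logical(1)))
      if (counts_ok) break
      if (iter == 60L) stop("could not build promoter for ", id)
    }
    promoters[id] <- s
    if (length(offs) > 0L)
      cis_truth[[length(cis_truth) + 1L]] <- data.frame(
        gene_id = id, element = pats, offset = offs, stringsAsFactors = FALSE)
  }
  cis_truth <- if (length(cis_truth) > 0L) do.call(rbind, cis_truth) else
    data.frame(gene_id = character(0), element = character(0),
               offset = integer(0))

  ## 7. assemble chromosomes and the GFF3 -------------------------------------
  strands <- stats::setNames(sample(c("+", "-"), n_genes, replace = TRUE),
                             gene_ids)
  intron_len <- config$intron_length
  make_body <- function(id) {
    # transcript-orientation body: CDS [intron] CDS-rest + UTR
    cdsq <- cds[[id]]
    has_intron <- id %in% intron_genes
    if (!has_intron)
      return(list(seq = paste0(cdsq, utr_seqs[id]),
                  exon_tr = cbind(1L, nchar(cdsq) + utr_len),
                  cds_tr = cbind(1L, nchar(cdsq)), intron = FALSE))
    n_cod <- nchar(cdsq) / 3L
    cut_codon <- sample(5:(n_cod - 5L), 1L)
    c1 <- cut_codon * 3L
    intron <- paste0("GT", clean_dna_no_ssr(intron_len - 4L), "AG")
    body <- paste0(substr(cdsq, 1L, c1), intron,
                   substr(cdsq, c1 + 1L, nchar(cdsq)), utr_seqs[id])
    list(seq = body,
         exon_tr = rbind(c(1L, c1),
                         c(c1 + intron_len + 1L,
                           nchar(cdsq) + intron_len + utr_len)),
         cds_tr = rbind(c(1L, c1),
                        c(c1 + intron_len + 1L, nchar(cdsq) + intron_len)),
         intron = TRUE)
  }
  chrom_seqs <- stats::setNames(rep("", length(chrom_names)), chrom_names)
  gff <- list(); gene_rows <- list()
  spacer <- config$spacer_length
  for (chr in chrom_names) {
    on_chr <- gene_ids[vapply(genes, function(g) g$chromosome == chr, logical(1))]
    pos <- 0L; parts <- character(0)
    for (id in on_chr) {
      body <- make_body(id)
      blen <- nchar(body$seq)
      parts <- c(parts, clean_dna(spacer, character(0)))
      pos <- pos + spacer
      if (strands[id] == "+") {
        parts <- c(parts, promoters[id], body$seq)
        g0 <- pos + prom_len + 1L
        gene_start <- g0; gene_end <- g0 + blen - 1L
        exons <- cbind(g0 + body$exon_tr[, 1L] - 1L, g0 + body$exon_tr[, 2L] - 1L)
        cds_rows <- cbind(g0 + body$cds_tr[, 1L] - 1L, g0 + body$cds_tr[, 2L] - 1L)
        pos <- pos + prom_len + blen
      } else {
        parts <- c(parts, revcomp(paste0(promoters[id], body$seq)))
        gene_start <- pos + 1L; gene_end <- pos + blen
        # transcript coordinate t -> genome gene_end - t + 1
        flip <- function(tr) {
          m <- cbind(gene_end - tr[, 2L] + 1L, gene_end - tr[, 1L] + 1L)
          m[order(m[, 1L]), , drop = FALSE]
        }
        exons <- flip(body$exon_tr)
        cds_rows <- flip(body$cds_tr)
        pos <- pos + blen + prom_len
      }
      gff[[length(gff) + 1L]] <- list(
        id = id, chr = chr, strand = strands[id],
        start = gene_start, end = gene_end, exons = exons, cds = cds_rows)
      gene_rows[[id]] <- list(start = gene_start, end = gene_end)
    }
    parts <- c(parts, clean_dna(spacer, character(0)))
    chrom_seqs[chr] <- paste(parts, collapse = "")
  }

  # SSR coordinates within the coding-orientation gene span (the sequence
  # the pipeline scans): the UTR is the final utr_len bp of the span.
  if (!is.null(ssr_truth) && nrow(ssr_truth) > 0L) {
    span_len <- vapply(ssr_truth$gene_id, function(id)
      gene_rows[[id]]$end - gene_rows[[id]]$start + 1, numeric(1))
    ssr_truth$span_start <- span_len - utr_len + ssr_truth$utr_start
  }

  ## 8. expression tables ------------------------------------------------------
  expr_cfg <- config$expression
  group_ids <- vapply(groups, `[[`, character(1), "group_id")
  expressed <- sample(group_ids, expr_cfg$n_expressed_groups)
  cols <- names(expr_cfg$columns)
  group_tpm <- matrix(0, length(group_ids), length(cols),
                      dimnames = list(group_ids, cols))
  for (g in group_ids) {
    if (g %in% expressed) {
      n_on <- sample(1:length(cols), 1L)
      on <- sample(cols, n_on)
      group_tpm[g, on] <- stats::runif(n_on, expr_cfg$tpm_range[1L],
                                       expr_cfg$tpm_range[2L])
      group_tpm[g, setdiff(cols, on)] <- stats::runif(length(cols) - n_on, 0, 0.8)
    } else {
      group_tpm[g, ] <- stats::runif(length(cols), 0, 0.5)
    }
  }
  members_of <- lapply(group_ids, function(g)
    gene_ids[vapply(genes, function(x) x$group_id == g, logical(1))])
  names(members_of) <- group_ids
  tpm <- matrix(0, n_genes, length(cols), dimnames = list(gene_ids, cols))
  for (g in group_ids) {
    m <- members_of[[g]]
    w <- stats::rgamma(length(m), shape = 5)
    w <- w / sum(w) * length(m)
    tpm[m, ] <- outer(w, group_tpm[g, ])
  }

  ## 9. qPCR table -------------------------------------------------------------
  qp <- config$qpcr
  qpcr_genes <- sample(gene_ids, qp$n_genes)
  qpcr_rows <- list(); qpcr_truth <- list()
  for (g in qpcr_genes) {
    base_dct <- stats::runif(1, 2, 5)
    for (cond in qp$conditions) {
      lfc <- stats::rnorm(length(qp$timepoints), 0, 2)
      strong <- sample(seq_along(qp$timepoints)[-1L], 1L)
      lfc[strong] <- sample(c(-1, 1), 1L) * qp$strong_fold_log2
      lfc[1L] <- 0
      for (t in seq_along(qp$timepoints)) {
        for (r in seq_len(qp$replicates)) {
          ct_ref <- stats::rnorm(1, 20, qp$ct_noise_sd)
          ct_tar <- ct_ref + base_dct - lfc[t] + stats::rnorm(1, 0, qp$ct_noise_sd)
          qpcr_rows[[length(qpcr_rows) + 1L]] <- data.frame(
            gene = g, condition = cond, timepoint = qp$timepoints[t],
            replicate = r, ct_target = ct_tar, ct_reference = ct_ref,
            stringsAsFactors = FALSE)
        }
        qpcr_truth[[length(qpcr_truth) + 1L]] <- data.frame(
          gene = g, condition = cond, timepoint = qp$timepoints[t],
          true_log2_rq = lfc[t], stringsAsFactors = FALSE)
      }
    }
  }
  qpcr_tab <- do.call(rbind, qpcr_rows)
  qpcr_truth <- do.call(rbind, qpcr_truth)

  ## 10. expected family names -------------------------------------------------
  grp_min_start <- vapply(groups, function(g) {
    min(vapply(members_of[[g$group_id]], function(id)
      gene_rows[[id]]$start + 0, numeric(1)))
  }, numeric(1))
  grp_min_sub <- vapply(groups, function(g)
    min(vapply(members_of[[g$group_id]],
               function(id) genes[[id]]$subgenome, character(1))), character(1))
  grp_cg <- vapply(groups, `[[`, numeric(1), "chrom_group")
  num_order <- order(grp_cg, grp_min_start, grp_min_sub)
  expected_names <- character(0)
  for (k in seq_along(num_order)) {
    g <- groups[[num_order[k]]]
    m <- members_of[[g$group_id]]
    chroms <- vapply(m, function(id) genes[[id]]$chromosome, character(1))
    for (chr in unique(chroms)) {
      ids <- m[chroms == chr]
      ids <- ids[order(vapply(ids, function(id) gene_rows[[id]]$start, numeric(1)))]
      expected_names[ids] <- if (length(ids) == 1L)
        paste0("VQ", k, "-", chr) else paste0("VQ", k, "-", chr, seq_along(ids))
    }
  }

  ## 11. write files ------------------------------------------------------------
  write_fasta(chrom_seqs, file.path(out_dir, "genome.fasta"))
  write_fasta(cds, file.path(out_dir, "cds.fasta"))
  write_fasta(proteins, file.path(out_dir, "proteins.fasta"))
  gff_lines <- c("##gff-version 3")
  for (g in gff) {
    a <- function(s, e, type, attrs)
      sprintf("%s\tvqsurvey\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              g$chr, type, s, e, g$strand,
              if (type == "CDS") "0" else ".", attrs)
    gff_lines <- c(gff_lines,
                   a(g$start, g$end, "gene", sprintf("ID=%s", g$id)),
                   a(g$start, g$end, "mRNA",
                     sprintf("ID=%s.t1;Parent=%s", g$id, g$id)))
    for (e in seq_len(nrow(g$exons)))
      gff_lines <- c(gff_lines, a(g$exons[e, 1L], g$exons[e, 2L], "exon",
                                  sprintf("ID=%s.e%d;Parent=%s.t1", g$id, e, g$id)))
    for (e in seq_len(nrow(g$cds)))
      gff_lines <- c(gff_lines, a(g$cds[e, 1L], g$cds[e, 2L], "CDS",
                                  sprintf("ID=%s.c%d;Parent=%s.t1", g$id, e, g$id)))
  }
  writeLines(gff_lines, file.path(out_dir, "annotation.gff3"))
  grp_tab <- data.frame(gene_id = gene_ids,
                        group_id = vapply(genes, `[[`, character(1), "group_id"))
  utils::write.table(grp_tab, file.path(out_dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tpm_out <- data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE)
  utils::write.table(tpm_out, file.path(out_dir, "tpm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(qpcr_tab, file.path(out_dir, "qpcr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## 12. manifest ----------------------------------------------------------------
  gene_manifest <- data.frame(
    gene_id = gene_ids,
    name = unname(expected_names[gene_ids]),
    group_id = vapply(genes, `[[`, character(1), "group_id"),
    category = vapply(genes, `[[`, character(1), "category"),
    chromosome = vapply(genes, `[[`, character(1), "chromosome"),
    strand = unname(strands[gene_ids]),
    start = vapply(gene_ids, function(id) gene_rows[[id]]$start, numeric(1)),
    end = vapply(gene_ids, function(id) gene_rows[[id]]$end, numeric(1)),
    variant = unname(ifelse(variants == "VTG_VH", "VTG", variants)),
    core = unname(ifelse(variants == "VTG_VH", "VH", "VQ")),
    canonical = unname(variants != "VMA"),
    motif_offset = unname(motif_offset[gene_ids]),
    n_introns = as.integer(gene_ids %in% intron_genes),
    protein_length = unname(nchar(proteins[gene_ids])),
    row.names = NULL, stringsAsFactors = FALSE)
  category_census <- do.call(rbind, lapply(names(config$ratio_census), function(cat) {
    pats <- config$ratio_census[[cat]]
    data.frame(category = cat, n_groups = length(pats),
               n_genes = sum(unlist(lapply(pats, sum))),
               stringsAsFactors = FALSE)
  }))
  dup_manifest <- do.call(rbind, lapply(pairs, function(p)
    data.frame(gene_a = p$a, gene_b = p$b, kind = p$kind,
               syn = p$syn, nonsyn = p$nonsyn, stringsAsFactors = FALSE)))
  cis_expected <- lapply(planted_elements, function(el)
    list(n_promoters = length(unique(cis_truth$gene_id[cis_truth$element == el])),
         carriers = sort(unique(cis_truth$gene_id[cis_truth$element == el]))))
  names(cis_expected) <- planted_elements
  manifest <- list(
    config = list(seed = config$seed, n_genes = n_genes,
                  n_groups = length(groups),
                  intronless_count = config$intronless_count,
                  promoter_length = prom_len),
    genes = gene_manifest,
    category_census = category_census,
    duplication_pairs = dup_manifest,
    ssrs = ssr_truth,
    cis = cis_truth,
    cis_expected = cis_expected,
    expressed_groups = sort(expressed),
    qpcr_truth = qpcr_truth)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
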