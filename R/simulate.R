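#' Configuration for the ground-truth library simulator
#'
#' The defaults emulate a deeply skewed plant seed small RNA library:
#' per-miRNA abundances drawn log-normally span roughly four orders of
#' magnitude, insert lengths are bimodal with peaks at 21 nt (canonical
#' plant miRNAs) and 24 nt (heterochromatic siRNA-like species),
#' contamination mixes structural-ncRNA fragments (removed by
#' subtraction) with degraded-mRNA fragments (which must survive
#' subtraction and fall through to the unmatched bins), and every insert
#' is followed by the Illumina small RNA 3' adapter read through to a
#' fixed 50-nt read length. The seed fully determines all outputs.
#'
#' @param seed integer seed; identical configs give byte-identical
#'   libraries.
#' @param total_reads library size in reads.
#' @param study_species species code of the simulated organism (kept out
#'   of the reference libraries, as for an unsequenced genome).
#' @param n_plant_species number of reference plant species (max 10).
#' @param n_families,members_per_family miRNA family structure of the
#'   simulated reference (`members_per_family` is an inclusive range).
#' @param star_fraction fraction of members simulated as miR/miR* duplexes
#'   (both arms planted; the star arm at ~5% of the mature weight).
#' @param conserved_fraction fraction of mature sequences copied under
#'   additional species codes to exercise conservation scoring.
#' @param family_length_classes mixing proportions of 21-nt-centred,
#'   24-nt-centred and broad (18-24 nt) families.
#' @param abundance_meanlog,abundance_sdlog log-normal abundance-weight
#'   parameters.
#' @param planted_counts optional explicit per-planted-miRNA read counts
#'   (overrides the log-normal draw; length must equal the number of
#'   planted arms, or 1 to recycle).
#' @param ncrna_fraction,degradation_fraction contaminant-read proportions.
#' @param n_animal,n_animal_homologs,animal_hamming animal library size,
#'   number of entries derived from plant miRNAs, and the Hamming
#'   distances sampled for them.
#' @param adapter 3' adapter appended to every insert (at least 5 nt).
#' @param read_length fixed sequencer read length.
#' @param error_rate per-base substitution probability.
#' @param quality_high,quality_error Phred scores written for correct and
#'   erroneous bases.
#' @return a `seedmir_sim_config` list.
#' @export
simulation_config <- function(seed = 1L, total_reads = 10000L,
                              study_species = "mol",
                              n_plant_species = 5L, n_families = 20L,
                              members_per_family = c(1L, 4L),
                              star_fraction = 0.3,
                              conserved_fraction = 0.4,
                              family_length_classes = c(mir21 = 0.6,
                                                        mir24 = 0.3,
                                                        broad = 0.1),
                              abundance_meanlog = log(300),
                              abundance_sdlog = 1.8,
                              planted_counts = NULL,
                              ncrna_fraction = 0.15,
                              degradation_fraction = 0.10,
                              n_animal = 15L, n_animal_homologs = 5L,
                              animal_hamming = 0:6,
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              read_length = 50L, error_rate = 0,
                              quality_high = 40L, quality_error = 14L) {
  if (nchar(adapter) < 5) {
    seedmir_abort("adapter must be at least 5 nt (clipping needs an anchor)",
                  "config")
  }
  fr <- c(ncrna_fraction, degradation_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    seedmir_abort("contamination fractions must lie in [0,1] and sum to <= 1",
                  "config")
  }
  stopifnot(n_plant_species >= 1, n_plant_species <= 10,
            length(members_per_family) == 2,
            members_per_family[1] >= 1,
            members_per_family[2] <= 26,
            error_rate >= 0, error_rate < 1,
            read_length >= 15)
  structure(
    list(seed = as.integer(seed), total_reads = as.integer(total_reads),
         study_species = study_species,
         n_plant_species = as.integer(n_plant_species),
         n_families = as.integer(n_families),
         members_per_family = as.integer(members_per_family),
         star_fraction = star_fraction,
         conserved_fraction = conserved_fraction,
         family_length_classes = family_length_classes,
         abundance_meanlog = abundance_meanlog,
         abundance_sdlog = abundance_sdlog,
         planted_counts = planted_counts,
         ncrna_fraction = ncrna_fraction,
         degradation_fraction = degradation_fraction,
         n_animal = as.integer(n_animal),
         n_animal_homologs = as.integer(n_animal_homologs),
         animal_hamming = as.integer(animal_hamming),
         adapter = adapter, read_length = as.integer(read_length),
         error_rate = error_rate,
         quality_high = as.integer(quality_high),
         quality_error = as.integer(quality_error)),
    class = "seedmir_sim_config")
}

rand_rna <- function(len) {
  vapply(len, function(L) {
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# TRUE when the 3' end of `s` equals an adapter prefix of >= min_overlap
# bases: such inserts would merge with the appended adapter and clip short.
has_adapter_suffix <- function(s, adapter_rna, min_overlap = 5L) {
  n <- nchar(s)
  top <- min(n, nchar(adapter_rna))
  if (top < min_overlap) return(FALSE)
  ks <- seq(min_overlap, top)
  any(vapply(ks, function(k) {
    substr(s, n - k + 1, n) == substr(adapter_rna, 1, k)
  }, logical(1)))
}

# Draw a random sequence that is unique, clip-safe and not an artifact.
draw_clean_seq <- function(len, taken, adapter_rna, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    s <- rand_rna(len)
    if (!s %in% taken && !has_adapter_suffix(s, adapter_rna) &&
        !is_artifact_seq(s)) {
      return(s)
    }
  }
  seedmir_abort("could not draw a clean sequence; length range too tight",
                "config")
}

plant_species_pool <- c("ath", "osa", "gma", "vvi", "ptc",
                        "zma", "sly", "mtr", "stu", "bdi")

#' Build simulated reference libraries with known structure
#'
#' Generates a plant mature-miRNA reference (with miR/miR* duplex arms,
#' and a configurable subset of sequences replicated under several species
#' codes so conservation rates have a planted truth), a structural-ncRNA
#' reference, decoy mRNA transcripts (the degradation source, deliberately
#' absent from every reference), and an animal miRNA library in which a
#' subset of entries sits at controlled Hamming distance from plant
#' miRNAs. All sequences are distinct, artifact-free and clip-safe so the
#' downstream cascade recovers planted counts exactly.
#'
#' @param config a [simulation_config()] list.
#' @return list with reference tibbles `plant`, `ncrna`, `animal`, decoy
#'   transcripts `decoys`, and `truth` (planted conservation multiplicities
#'   and animal homolog distances).
#' @export
build_references <- function(config) {
  withr::with_seed(config$seed, build_references_impl(config))
}

build_references_impl <- function(config) {
  adapter_rna <- normalize_sequence(config$adapter)
  species <- head(plant_species_pool, config$n_plant_species)
  fam_ids <- sort(sample(100:9999, config$n_families))
  fam_names <- paste0("miR", fam_ids)
  fam_class <- sample(names(config$family_length_classes),
                      config$n_families, replace = TRUE,
                      prob = config$family_length_classes)
  draw_len <- function(class) {
    switch(class,
           mir21 = sample(20:22, 1, prob = c(0.15, 0.70, 0.15)),
           mir24 = sample(23:24, 1, prob = c(0.1, 0.9)),
           broad = sample(18:24, 1))
  }

  taken <- character(0)
  rows <- list()
  acc <- 0L
  add_entry <- function(species_code, name, sequence, arm) {
    acc <<- acc + 1L
    rows[[length(rows) + 1]] <<- tibble(
      accession = sprintf("SIM%05d", acc), species_code = species_code,
      name = name, family = derive_family(name), rna_class = "miRNA",
      sequence = sequence, arm = arm)
  }

  cons_truth <- list()
  for (f in seq_len(config$n_families)) {
    n_mem <- sample(seq(config$members_per_family[1],
                        config$members_per_family[2]), 1)
    mem_names <- if (n_mem == 1) fam_names[f] else
      paste0(fam_names[f], letters[seq_len(n_mem)])
    for (mem in mem_names) {
      len <- draw_len(fam_class[f])
      mature <- draw_clean_seq(len, taken, adapter_rna)
      taken <- c(taken, mature)
      duplex <- runif(1) < config$star_fraction
      primary <- sample(species, 1)
      extra <- if (config$n_plant_species > 1 &&
                   runif(1) < config$conserved_fraction) {
        sample(setdiff(species, primary),
               sample(config$n_plant_species - 1L, 1))
      } else {
        character(0)
      }
      # arm annotation must survive a FASTA round trip, so it lives in the
      # name suffix: duplex members get -5p/-3p, single-arm ones stay bare
      mname <- if (duplex) paste0(mem, "-5p") else mem
      marm <- if (duplex) "mature" else "unspecified"
      for (sp in c(primary, extra)) add_entry(sp, mname, mature, marm)
      cons_truth[[length(cons_truth) + 1]] <-
        tibble(sequence = mature, n_entries = 1L + length(extra))
      if (duplex) {
        star <- reverse_complement(mature)
        if (star %in% taken || has_adapter_suffix(star, adapter_rna) ||
            is_artifact_seq(star)) {
          star <- draw_clean_seq(len, taken, adapter_rna)
        }
        taken <- c(taken, star)
        add_entry(primary, paste0(mem, "-3p"), star, "star")
        cons_truth[[length(cons_truth) + 1]] <-
          tibble(sequence = star, n_entries = 1L)
      }
    }
  }
  plant <- bind_rows(rows)

  # Structural ncRNAs: long enough that contaminant tags are proper
  # substrings; regenerated if any planted miRNA lies inside them.
  ncrna_spec <- tibble(
    rna_class = c("rRNA", "rRNA", "tRNA", "tRNA", "tRNA",
                  "snRNA", "snRNA", "snoRNA", "snoRNA"),
    len = c(sample(400:800, 2, replace = TRUE),
            sample(70:90, 3, replace = TRUE),
            sample(100:180, 2, replace = TRUE),
            sample(80:140, 2, replace = TRUE)))
  draw_long <- function(len) {
    for (i in 1:50) {
      s <- rand_rna(len)
      if (!any(stringi::stri_detect_fixed(s, plant$sequence))) return(s)
    }
    seedmir_abort("could not draw a clean long sequence", "config")
  }
  ncrna <- ncrna_spec |>
    group_by(.data$rna_class) |>
    mutate(idx = dplyr::row_number()) |>
    ungroup() |>
    mutate(accession = sprintf("SIMNC%03d", dplyr::row_number()),
           species_code = "sim",
           name = paste0(.data$rna_class, .data$idx),
           family = NA_character_,
           sequence = vapply(.data$len, draw_long, character(1)),
           arm = "unspecified") |>
    select("accession", "species_code", "name", "family", "rna_class",
           "sequence", "arm")

  decoys <- tibble(name = paste0("decoy_mRNA", 1:3),
                   sequence = vapply(sample(500:900, 3, replace = TRUE),
                                     draw_long, character(1)))

  # Animal library: some entries mutated copies of plant matures.
  matures <- dplyr::filter(plant, .data$arm == "mature") |>
    distinct(.data$name, .data$sequence) |>
    dplyr::filter(nchar(.data$sequence) >= 17)
  n_hom <- min(config$n_animal_homologs, nrow(matures), config$n_animal)
  hom_idx <- sample(nrow(matures), n_hom)
  animal_rows <- list()
  pair_truth <- list()
  a_taken <- taken
  for (i in seq_len(n_hom)) {
    src <- matures$sequence[hom_idx[i]]
    d <- sample(config$animal_hamming, 1)
    s <- strsplit(src, "", fixed = TRUE)[[1]]
    if (d > 0) {
      pos <- sample(length(s), min(d, length(s)))
      for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "U"), s[p]), 1)
    }
    aseq <- paste(s, collapse = "")
    aname <- sprintf("miR%d-hom", 10000 + i)
    animal_rows[[i]] <- tibble(
      accession = sprintf("SIMAN%03d", i), species_code = "hsa",
      name = aname, family = derive_family(aname), rna_class = "miRNA",
      sequence = aseq, arm = "unspecified")
    pair_truth[[i]] <- tibble(
      animal_name = paste0("hsa-", aname),
      plant_name = matures$name[hom_idx[i]],
      plant_sequence = src, animal_sequence = aseq,
      hamming = min(d, nchar(src)))
    a_taken <- c(a_taken, aseq)
  }
  n_rand <- config$n_animal - n_hom
  for (i in seq_len(n_rand)) {
    aseq <- draw_clean_seq(sample(19:23, 1), a_taken, adapter_rna)
    a_taken <- c(a_taken, aseq)
    aname <- sprintf("miR%d", 20000 + i)
    animal_rows[[n_hom + i]] <- tibble(
      accession = sprintf("SIMAN%03d", n_hom + i), species_code = "hsa",
      name = aname, family = derive_family(aname), rna_class = "miRNA",
      sequence = aseq, arm = "unspecified")
  }

  list(plant = plant, ncrna = ncrna, animal = bind_rows(animal_rows),
       decoys = decoys,
       truth = list(conservation = bind_rows(cons_truth),
                    animal_pairs = bind_rows(pair_truth)))
}

#' Simulate a small RNA sequencing library with known truth
#'
#' Each read is an insert (a planted miRNA arm, a structural-ncRNA
#' fragment, or a degraded-mRNA fragment) followed by the 3' adapter,
#' padded with random bases or truncated to the fixed read length. With
#' `error_rate` 0 every planted read's insert equals its reference
#' sequence exactly, so the truth manifest gives exact expected counts for
#' every downstream stage. Planted counts sum to
#' `(1 - contamination fractions) * total_reads` by construction.
#'
#' @param config a [simulation_config()] list.
#' @param references output of [build_references()] (or compatible
#'   user-supplied list).
#' @param fastq optional path: write the library as a DNA-alphabet FASTQ.
#' @param manifest_path optional path: write the truth manifest as TSV.
#' @return list with `reads` (tibble as from [read_fastq()]) and
#'   `manifest` (per planted arm: species, name, family, arm, sequence,
#'   count; plus one row per contaminant class).
#' @export
simulate_library <- function(config, references, fastq = NULL,
                             manifest_path = NULL) {
  out <- withr::with_seed(config$seed + 1L,
                          simulate_library_impl(config, references))
  if (!is.null(fastq)) write_fastq(out$reads, fastq, alphabet = "dna")
  if (!is.null(manifest_path)) {
    readr::write_tsv(out$manifest, manifest_path, progress = FALSE)
  }
  out
}

simulate_library_impl <- function(config, references) {
  adapter_rna <- normalize_sequence(config$adapter)

  # Planted units: one per distinct expressed sequence; shared (conserved)
  # sequences are expressed once by the study organism. The representative
  # labelling matches the annotation tie-break so truth aligns with calls.
  planted <- references$plant |>
    arrange(.data$species_code, .data$name) |>
    distinct(.data$sequence, .keep_all = TRUE) |>
    arrange(.data$name, .data$sequence)

  if (!is.null(config$planted_counts)) {
    counts <- as.integer(config$planted_counts)
    if (length(counts) == 1) counts <- rep(counts, nrow(planted))
    if (length(counts) != nrow(planted)) {
      seedmir_abort(sprintf(
        "planted_counts has length %d but there are %d planted arms",
        length(counts), nrow(planted)), "config")
    }
    n_planted <- sum(counts)
    total <- as.integer(round(n_planted /
      (1 - config$ncrna_fraction - config$degradation_fraction)))
    n_nc <- as.integer(round(config$ncrna_fraction * total))
    n_deg <- total - n_planted - n_nc
  } else {
    total <- config$total_reads
    n_nc <- as.integer(round(config$ncrna_fraction * total))
    n_deg <- as.integer(round(config$degradation_fraction * total))
    n_planted <- total - n_nc - n_deg
    # Heavy-tailed abundances, with the largest draws landing on 21-nt and
    # then 24-nt species: in real plant libraries the dominant reads are
    # canonical 21-nt miRNAs and 24-nt siRNA-like RNAs, and an uncoupled
    # draw would let any length class win the library by chance.
    w <- sort(rlnorm(nrow(planted), config$abundance_meanlog,
                     config$abundance_sdlog), decreasing = TRUE)
    len <- nchar(planted$sequence)
    priority <- ifelse(len == 21, 1L, ifelse(len == 24, 2L, 3L))
    weights <- numeric(nrow(planted))
    weights[order(priority, runif(nrow(planted)))] <- w
    weights[planted$arm == "star"] <- weights[planted$arm == "star"] * 0.05
    counts <- largest_remainder(weights, n_planted)
  }

  frag <- function(sources, len_range, n) {
    if (n == 0) return(character(0))
    src_len <- nchar(sources)
    vapply(seq_len(n), function(i) {
      for (try in 1:100) {
        j <- sample(length(sources), 1)
        L <- sample(seq(len_range[1], min(len_range[2], src_len[j])), 1)
        start <- sample(src_len[j] - L + 1L, 1)
        s <- substr(sources[j], start, start + L - 1L)
        if (!has_adapter_suffix(s, adapter_rna) && !is_artifact_seq(s)) {
          return(s)
        }
      }
      seedmir_abort("could not draw a clean contaminant fragment", "config")
    }, character(1))
  }

  inserts <- c(rep(planted$sequence, counts),
               frag(references$ncrna$sequence, c(16, 28), n_nc),
               frag(references$decoys$sequence, c(15, 35), n_deg))
  stopifnot(length(inserts) == total)

  reads_rna <- paste0(inserts, adapter_rna)
  short <- nchar(reads_rna) < config$read_length
  if (any(short)) {
    pad_n <- config$read_length - nchar(reads_rna[short])
    reads_rna[short] <- paste0(reads_rna[short], rand_rna(pad_n))
  }
  reads_rna <- substr(reads_rna, 1, config$read_length)
  qual <- strrep(intToUtf8(33L + config$quality_high), config$read_length)
  quals <- rep(qual, total)

  if (config$error_rate > 0) {
    err_char <- intToUtf8(33L + config$quality_error)
    for (i in seq_len(total)) {
      hit <- which(runif(config$read_length) < config$error_rate)
      if (!length(hit)) next
      s <- strsplit(reads_rna[i], "", fixed = TRUE)[[1]]
      q <- strsplit(quals[i], "", fixed = TRUE)[[1]]
      for (p in hit) {
        s[p] <- sample(setdiff(c("A", "C", "G", "U"), s[p]), 1)
        q[p] <- err_char
      }
      reads_rna[i] <- paste(s, collapse = "")
      quals[i] <- paste(q, collapse = "")
    }
  }

  ord <- sample(total)
  reads <- tibble(read_id = sprintf("sim_%07d", seq_len(total)),
                  sequence = reads_rna[ord], quality = quals[ord])

  manifest <- bind_rows(
    tibble(class = "mirna",
           species_code = planted$species_code, name = planted$name,
           family = planted$family, arm = planted$arm,
           sequence = planted$sequence, count = counts),
    tibble(class = "ncrna", species_code = NA, name = NA, family = NA,
           arm = NA, sequence = NA, count = n_nc),
    tibble(class = "degradation", species_code = NA, name = NA,
           family = NA, arm = NA, sequence = NA, count = n_deg))

  list(reads = reads, manifest = manifest)
}
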