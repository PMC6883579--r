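# Synthetic study material: small taxonomies with sister strains, species
# and genera; genomes diverged from a common ancestor by per-level point
# substitution; and 100 bp paired-end reads with a configurable error
# profile.  Everything is deterministic given the seed, so the
# strain-exclusion experiments need no external downloads.

random_genome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_genome <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) > 0) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      chars[i] <- sample(setdiff(bases, chars[i]), 1)
    }
  }
  paste(chars, collapse = "")
}

revcomp <- function(seq) .revcomp_dna_cpp(seq)

#' Generate a synthetic world of related genomes
#'
#' Builds a four-level taxonomy (one domain root, then genera, species,
#' strains), evolves genomes down the tree by independent per-base
#' substitution at a per-level rate, and returns the strain genomes with
#' their taxonomy.  Defaults place sister strains at 0.5% divergence,
#' sister species at 2%, and sister genera at 10% (cumulative down the
#' tree), which makes genus-level classification comfortably learnable at
#' desk scale while strain-level identity stays ambiguous -- the regime the
#' strain-exclusion benchmark probes.
#'
#' With the default three strains per species and three species per genus,
#' every strain has at least two sister strains and every species at least
#' two sister species, so any strain is eligible for exclusion.
#'
#' @param n_genera,species_per_genus,strains_per_species tree shape
#'   (all >= 1).
#' @param genome_len genome length in bases.
#' @param divergence named numeric vector of per-level substitution rates
#'   `c(genus=, species=, strain=)`, each in [0, 0.5).
#' @param seed integer master seed.
#' @return an object of class `synthetic_world`: `tree` (a
#'   [taxonomy_tree()]), `genomes` (named character, strain external ID ->
#'   sequence), `strains`, `seed`.
#' @export
make_world <- function(n_genera = 2, species_per_genus = 3,
                       strains_per_species = 3, genome_len = 1e5,
                       divergence = c(genus = 0.10, species = 0.02,
                                      strain = 0.005),
                       seed = 1L) {
  stopifnot(n_genera >= 1, species_per_genus >= 1, strains_per_species >= 1,
            all(divergence >= 0), all(divergence < 0.5))
  set.seed(seed)
  nodes <- data.frame(external_id = 1L, parent_external = 1L,
                      rank = "domain", name = "root domain",
                      stringsAsFactors = FALSE)
  genomes <- character(0)
  root_genome <- random_genome(genome_len)
  genus_id <- 100L; species_id <- 1000L; strain_id <- 10000L
  for (g in seq_len(n_genera)) {
    genus_id <- genus_id + 1L
    nodes <- rbind(nodes, data.frame(
      external_id = genus_id, parent_external = 1L, rank = "genus",
      name = paste("genus", g), stringsAsFactors = FALSE))
    genus_genome <- mutate_genome(root_genome, divergence[["genus"]])
    for (s in seq_len(species_per_genus)) {
      species_id <- species_id + 1L
      nodes <- rbind(nodes, data.frame(
        external_id = species_id, parent_external = genus_id,
        rank = "species", name = paste0("species ", g, ".", s),
        stringsAsFactors = FALSE))
      species_genome <- mutate_genome(genus_genome, divergence[["species"]])
      for (t in seq_len(strains_per_species)) {
        strain_id <- strain_id + 1L
        nodes <- rbind(nodes, data.frame(
          external_id = strain_id, parent_external = species_id,
          rank = "strain", name = paste0("strain ", g, ".", s, ".", t),
          stringsAsFactors = FALSE))
        genomes[[as.character(strain_id)]] <-
          mutate_genome(species_genome, divergence[["strain"]])
      }
    }
  }
  structure(list(tree = taxonomy_tree(nodes), genomes = genomes,
                 strains = as.integer(names(genomes)), seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic world: %d taxa, %d strain genomes of %d bp\n",
              nrow(x$tree$nodes), length(x$genomes),
              nchar(x$genomes[[1]])))
  invisible(x)
}

# Build one read from a template window, applying substitution and indel
# errors base by base.  Returns the read and the realized error counts.
build_read_errors <- function(template_chars, read_len, p_mis, p_ins, p_del) {
  out <- character(read_len)
  bases <- c("A", "C", "G", "T")
  ti <- 1L; i <- 1L; n_mis <- 0L; n_ins <- 0L; n_del <- 0L
  while (i <= read_len) {
    u <- runif(1)
    if (u < p_ins) {
      out[i] <- sample(bases, 1); n_ins <- n_ins + 1L; i <- i + 1L
    } else if (u < p_ins + p_del) {
      ti <- ti + 1L; n_del <- n_del + 1L
    } else {
      # deletions can run past the slack window at a genome edge; pad
      b <- if (ti <= length(template_chars)) template_chars[ti]
           else sample(bases, 1)
      if (runif(1) < p_mis) { b <- sample(setdiff(bases, b), 1)
                              n_mis <- n_mis + 1L }
      out[i] <- b
      ti <- ti + 1L; i <- i + 1L
    }
  }
  list(seq = paste(out, collapse = ""), n_mis = n_mis, n_ins = n_ins,
       n_del = n_del)
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are drawn uniformly along the genome with a random strand;
#' mate 1 is sequenced from the 5' end of the chosen strand and mate 2 is
#' the reverse complement of the other end.  Per-base sequencing errors
#' are applied independently at the given rates (defaults: 0.4%
#' mismatches, 0.005% insertions, 0.005% deletions).  Read names embed the
#' fragment index; full origin coordinates, strand, and realized error
#' counts per mate are returned in the truth table.  Quality strings are a
#' constant placeholder (the classifier ignores qualities).
#'
#' @param genome character scalar.
#' @param n_fragments number of fragments (read pairs).
#' @param read_len read length (default 100).
#' @param frag_mean,frag_sd fragment length distribution (normal, clipped
#'   to `[read_len, genome length - 10]`).
#' @param mismatch,ins,del per-base error rates.
#' @param taxid external taxon recorded in the truth table.
#' @param id_prefix prefix of read names.
#' @param seed optional seed (`set.seed` is called when non-NULL).
#' @return list with `reads1`, `reads2` (data.frames `id`, `seq`, `qual`)
#'   and `truth` (data.frame with `fragment_id`, `taxid`, fragment
#'   coordinates, strand, and per-mate error counts).
#' @export
simulate_reads <- function(genome, n_fragments, read_len = 100,
                           frag_mean = 300, frag_sd = 25,
                           mismatch = 0.004, ins = 5e-5, del = 5e-5,
                           taxid = NA_integer_, id_prefix = "frag",
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  glen <- nchar(genome)
  slack <- 10L
  if (glen < frag_mean + slack)
    stop("genome shorter than the mean fragment length")
  flen <- pmin(pmax(round(rnorm(n_fragments, frag_mean, frag_sd)),
                    read_len), glen - slack)
  fstart <- floor(runif(n_fragments, 1, glen - flen - slack + 1))
  strand <- sample(c("+", "-"), n_fragments, replace = TRUE)
  ids <- sprintf("%s%06d", id_prefix, seq_len(n_fragments))
  r1 <- character(n_fragments); r2 <- character(n_fragments)
  err <- matrix(0L, n_fragments, 6,
                dimnames = list(NULL, c("n_mis1", "n_ins1", "n_del1",
                                        "n_mis2", "n_ins2", "n_del2")))
  for (i in seq_len(n_fragments)) {
    # template windows (with indel slack) at the two fragment ends
    left <- substr(genome, fstart[i], fstart[i] + read_len + slack - 1L)
    right_start <- fstart[i] + flen[i] - read_len
    right <- revcomp(substr(genome, right_start - slack + 1L,
                            right_start + read_len - 1L))
    if (strand[i] == "+") { t1 <- left; t2 <- right }
    else { t1 <- right; t2 <- left }
    e1 <- build_read_errors(strsplit(t1, "")[[1]], read_len, mismatch, ins,
                            del)
    e2 <- build_read_errors(strsplit(t2, "")[[1]], read_len, mismatch, ins,
                            del)
    r1[i] <- e1$seq; r2[i] <- e2$seq
    err[i, ] <- c(e1$n_mis, e1$n_ins, e1$n_del, e2$n_mis, e2$n_ins,
                  e2$n_del)
  }
  qual <- strrep("I", read_len)
  truth <- data.frame(fragment_id = ids, taxid = taxid, start = fstart,
                      frag_len = flen, strand = strand,
                      err, stringsAsFactors = FALSE)
  list(reads1 = data.frame(id = ids, seq = r1, qual = qual,
                           stringsAsFactors = FALSE),
       reads2 = data.frame(id = ids, seq = r2, qual = qual,
                           stringsAsFactors = FALSE),
       truth = truth)
}

# Template substring a mate was copied from (before errors), used for
# calibration of the simulator's error rates.
mate_template <- function(genome, truth_row, mate, read_len) {
  left <- substr(genome, truth_row$start, truth_row$start + read_len - 1L)
  right_start <- truth_row$start + truth_row$frag_len - read_len
  right <- revcomp(substr(genome, right_start,
                          right_start + read_len - 1L))
  if (truth_row$strand == "+") { if (mate == 1) left else right }
  else { if (mate == 1) right else left }
}

#' Measure the realized per-base mismatch rate of simulated reads
#'
#' Compares each read base to its known template base using the recorded
#' origin coordinates.  Mates whose error record contains an insertion or
#' deletion are excluded (their bases are shifted relative to the
#' template, so a positional comparison would misattribute the shift as
#' mismatches); at default rates this discards about 1 mate in 100.
#'
#' @param sim a [simulate_reads()] result.
#' @param genome the genome the reads were simulated from.
#' @return list with `mismatch_rate` (fraction), `mismatches`, `bases`.
#' @export
measure_mismatch_rate <- function(sim, genome) {
  read_len <- nchar(sim$reads1$seq[1])
  mismatches <- 0; bases <- 0
  for (i in seq_len(nrow(sim$truth))) {
    row <- sim$truth[i, ]
    for (mate in 1:2) {
      if (mate == 1 && (row$n_ins1 > 0 || row$n_del1 > 0)) next
      if (mate == 2 && (row$n_ins2 > 0 || row$n_del2 > 0)) next
      tmpl <- mate_template(genome, row, mate, read_len)
      read <- if (mate == 1) sim$reads1$seq[i] else sim$reads2$seq[i]
      a <- strsplit(tmpl, "")[[1]]; b <- strsplit(read, "")[[1]]
      mismatches <- mismatches + sum(a != b)
      bases <- bases + read_len
    }
  }
  list(mismatch_rate = mismatches / bases, mismatches = mismatches,
       bases = bases)
}

#' Run a strain-exclusion experiment
#'
#' Builds a database from all strain genomes except the held-out ones,
#' simulates reads from the held-out strains, classifies them, and
#' categorizes every fragment at the requested ranks against the full
#' (unpruned) taxonomy.  A held-out strain without at least one sister
#' strain in the database is refused, since a true positive would then be
#' impossible by construction.
#'
#' @param world a [make_world()] result.
#' @param held_out integer vector of strain external IDs to exclude.
#' @param scheme a [minimizer_scheme()].
#' @param n_fragments fragments simulated per held-out strain.
#' @param ranks character vector of evaluation ranks.
#' @param read_config list of arguments forwarded to [simulate_reads()].
#' @param max_cells optional table-size cap forwarded to
#'   [build_database()].
#' @param seed integer master seed (world genomes are fixed already; this
#'   seeds read simulation).
#' @return list with `counts` (per-rank [accuracy_counts()]), `metrics`
#'   (per-rank data.frame of sensitivity/PPV/F1), `db_cells`,
#'   `n_fragments`.
#' @export
strain_exclusion_experiment <- function(world, held_out, scheme,
                                        n_fragments = 200,
                                        ranks = c("species", "genus"),
                                        read_config = list(),
                                        max_cells = NULL, seed = 1L) {
  held_out <- as.integer(held_out)
  stopifnot(all(held_out %in% world$strains))
  par <- parent_lookup(world$tree)
  for (h in held_out) {
    sisters <- setdiff(world$strains[
      par[as.character(world$strains)] == par[[as.character(h)]]],
      c(h, held_out))
    if (length(sisters) == 0)
      stop("held-out strain ", h, " has no sister strain left in the ",
           "reference; a true positive would be impossible")
  }
  included <- setdiff(world$strains, held_out)
  library <- setNames(world$genomes[as.character(included)],
                      paste0("strain", included))
  taxon_map <- setNames(included, names(library))
  db <- build_database(library, taxon_map, world$tree, scheme,
                       max_cells = max_cells)

  set.seed(seed)
  truth <- integer(0)
  pred <- integer(0)
  for (h in held_out) {
    sim <- do.call(simulate_reads,
                   c(list(genome = world$genomes[[as.character(h)]],
                          n_fragments = n_fragments, taxid = h,
                          id_prefix = paste0("s", h, "_")),
                     read_config))
    cls <- classify_reads(db, sim$reads1, sim$reads2)
    truth <- c(truth, rep(h, n_fragments))
    pred <- c(pred, vapply(cls, `[[`, 0L, "external_taxon"))
  }
  counts <- lapply(ranks, function(r)
    accuracy_counts(truth, pred, r, world$tree))
  names(counts) <- ranks
  metrics <- do.call(rbind, lapply(ranks, function(r) {
    m <- accuracy_metrics(counts[[r]])
    data.frame(rank = r, TP = counts[[r]]["TP"], VP = counts[[r]]["VP"],
               FN = counts[[r]]["FN"], FP = counts[[r]]["FP"],
               sensitivity = m$sensitivity, ppv = m$ppv, f1 = m$f1,
               row.names = NULL)
  }))
  list(counts = counts, metrics = metrics,
       db_cells = cht_info(db$table)$cell_count,
       n_fragments = length(truth))
}

#' Materialize a world on disk
#'
#' Writes the reference library FASTA, the `seqid -> taxid` TSV, the
#' taxonomy in NCBI dump dialect, simulated paired FASTQ reads for the
#' requested strains, and the truth TSV into one directory.
#'
#' @param world a [make_world()] result.
#' @param dir output directory.
#' @param read_strains strains to simulate reads from (default: none).
#' @param n_fragments fragments per strain.
#' @param seed read-simulation seed.
#' @return invisibly, `dir`.
#' @export
write_world <- function(world, dir, read_strains = integer(0),
                        n_fragments = 100, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- data.frame(id = paste0("strain", world$strains),
                    seq = unname(world$genomes[as.character(world$strains)]),
                    stringsAsFactors = FALSE)
  write_fasta(lib, file.path(dir, "library.fna"))
  write.table(data.frame(id = lib$id, taxid = world$strains),
              file.path(dir, "seqid2taxid.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_taxonomy_dump(world$tree, file.path(dir, "nodes.dmp"),
                      file.path(dir, "names.dmp"))
  if (length(read_strains) > 0) {
    set.seed(seed)
    all_truth <- list(); r1 <- list(); r2 <- list()
    for (h in read_strains) {
      sim <- simulate_reads(world$genomes[[as.character(h)]], n_fragments,
                            taxid = h, id_prefix = paste0("s", h, "_"))
      all_truth[[length(all_truth) + 1L]] <- sim$truth
      r1[[length(r1) + 1L]] <- sim$reads1
      r2[[length(r2) + 1L]] <- sim$reads2
    }
    write_fastq(do.call(rbind, r1), file.path(dir, "reads_1.fastq"))
    write_fastq(do.call(rbind, r2), file.path(dir, "reads_2.fastq"))
    truth <- do.call(rbind, all_truth)
    write.table(truth[, c("fragment_id", "taxid")],
                file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
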