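`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracles.  These deliberately avoid the package's
# indexing / enumeration code paths: the scanner oracle works from spliced
# transcript strings alone, the Fisher oracle from stats::dhyper, and the
# pedigree oracle from a full 3^n genotype grid.

# All-splits / all-junction-pairs scan of a single read.
oracle_scan <- function(read, genes, genome, k = 20L,
                        require_distinct_genes = TRUE,
                        scan_revcomp = TRUE) {
  txs <- unique(genes$transcript_id)
  seqs <- spliced_sequence(genes, genome, txs)
  junc <- do.call(rbind, lapply(txs, function(tx) {
    e <- genes[genes$transcript_id == tx, , drop = FALSE]
    e <- e[order(e$exon_rank), , drop = FALSE]
    if (nrow(e) < 2L) return(NULL)
    cum <- cumsum(e$end - e$start + 1L)
    plus <- e$strand[1L] == "+"
    n <- nrow(e)
    data.frame(gene = e$gene_id[1L], tx = tx, intron = seq_len(n - 1L),
               off = cum[-n],
               donor_coord = if (plus) e$end[-n] else e$start[-n],
               acceptor_coord = if (plus) e$start[-1L] else e$end[-1L],
               stringsAsFactors = FALSE)
  }))
  hit1 <- function(r, orient) {
    len <- nchar(r)
    out <- list()
    for (p in seq.int(k, len - k)) {
      pre <- substring(r, 1L, p); suf <- substring(r, p + 1L, len)
      for (i in seq_len(nrow(junc))) {
        P <- substring(seqs[[junc$tx[i]]], 1L, junc$off[i])
        if (nchar(P) < p || !endsWith(P, pre)) next
        for (j in seq_len(nrow(junc))) {
          if (require_distinct_genes && junc$gene[i] == junc$gene[j]) next
          S <- substring(seqs[[junc$tx[j]]], junc$off[j] + 1L,
                         nchar(seqs[[junc$tx[j]]]))
          if (nchar(S) < len - p || !startsWith(S, suf)) next
          out[[length(out) + 1L]] <- data.frame(
            orientation = orient, split_offset = p,
            donor_gene = junc$gene[i], donor_coord = junc$donor_coord[i],
            acceptor_gene = junc$gene[j],
            acceptor_coord = junc$acceptor_coord[j],
            stringsAsFactors = FALSE)
        }
      }
    }
    out
  }
  res <- c(hit1(read, "forward"),
           if (scan_revcomp) hit1(splicekey:::revcomp(read), "revcomp"))
  if (length(res) == 0L) return(NULL)
  unique(do.call(rbind, res))
}

# Exact two-sided Fisher p (minimum-likelihood convention) via dhyper.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  supp <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(supp, r1, r2, c1)
  pobs <- pr[supp == a]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# Full 3^n pedigree enumeration.  Returns the matrix of consistent genotype
# assignments (columns = individuals in ped row order).
oracle_ped_assignments <- function(ped) {
  n <- nrow(ped)
  grid <- as.matrix(expand.grid(rep(list(0:2), n)))
  colnames(grid) <- ped$id
  trans <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
  ok <- rep(TRUE, nrow(grid))
  for (i in seq_len(n)) {
    ph <- ped$phenotype[i]
    if (ph == "positive") ok <- ok & grid[, i] >= 1L
    if (ph == "negative") ok <- ok & grid[, i] == 0L
    if (!is.na(ped$genotype[i]))
      ok <- ok & grid[, i] == c(`-/-` = 0L, `+/-` = 1L,
                                `+/+` = 2L)[[ped$genotype[i]]]
  }
  fa <- match(ped$father, ped$id); mo <- match(ped$mother, ped$id)
  for (i in seq_len(n)) {
    if (is.na(fa[i]) && is.na(mo[i])) next
    comp <- vapply(which(ok), function(r) {
      pa <- if (!is.na(fa[i])) trans[[as.character(grid[r, fa[i]])]] else 0:1
      pb <- if (!is.na(mo[i])) trans[[as.character(grid[r, mo[i]])]] else 0:1
      any(outer(pa, pb, `+`) == grid[r, i])
    }, logical(1))
    ok[which(ok)] <- comp
  }
  grid[ok, , drop = FALSE]
}

oracle_ped_possible <- function(ped) {
  m <- oracle_ped_assignments(ped)
  lab <- c(`0` = "-/-", `1` = "+/-", `2` = "+/+")
  lapply(stats::setNames(seq_len(nrow(ped)), ped$id),
         function(i) unname(lab[as.character(sort(unique(m[, i])))]))
}

oracle_ped_swaps <- function(ped) {
  if (nrow(oracle_ped_assignments(ped)) > 0L) return(NULL)
  n <- nrow(ped)
  out <- list()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (ped$phenotype[i] == ped$phenotype[j]) next
    p2 <- ped
    p2$phenotype[c(i, j)] <- p2$phenotype[c(j, i)]
    p2$genotype[c(i, j)] <- p2$genotype[c(j, i)]
    if (nrow(oracle_ped_assignments(p2)) > 0L)
      out[[length(out) + 1L]] <- sort(c(ped$id[i], ped$id[j]))
  }
  out
}

# Random small pedigree for oracle comparisons (acyclic by construction).
random_pedigree <- function(n, seed) {
  set.seed(seed)
  id <- sprintf("P%02d", seq_len(n))
  father <- rep(NA_character_, n); mother <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3L && stats::runif(1) < 0.6) {
      fi <- sample.int(i - 1L, 1L)
      cand <- setdiff(seq_len(i - 1L), fi)
      father[i] <- id[fi]
      mother[i] <- id[cand[sample.int(length(cand), 1L)]]
    }
  }
  as_pedigree(data.frame(
    id = id, father = father, mother = mother,
    sex = sample(c("M", "F"), n, replace = TRUE),
    phenotype = sample(c("positive", "negative", "unknown"), n,
                       replace = TRUE, prob = c(0.45, 0.45, 0.1)),
    stringsAsFactors = FALSE))
}
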