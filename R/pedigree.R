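#' Construct / validate a pedigree with fusion phenotypes
#'
#' The fusion marker is modelled as a single autosomal biallelic dominant
#' presence locus: genotype in \{+/+, +/-, -/-\}, phenotype positive iff at
#' least one + allele, no de-novo events.  Columns: `id`, `father`, `mother`
#' (`NA`/`""`/`"0"` for founders), `sex` (`M`/`F`/`unknown`), `phenotype`
#' (`positive`/`negative`/`unknown`).  Optional columns: `genotype` — a
#' known genotype (e.g. from WGS zygosity), which constrains inference
#' beyond the phenotype; `evidence` (`RNA`/`WGS`/`both`), informational.
#'
#' @param df Data frame with the columns above.
#' @return Validated data frame of class `pedigree` (topologically sorted,
#'   parents before children).
#' @export
as_pedigree <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("id", "father", "mother", "sex", "phenotype")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pedigree lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(df$genotype)) df$genotype <- NA_character_
  if (is.null(df$evidence)) df$evidence <- NA_character_
  norm <- function(x) { x <- as.character(x); x[x %in% c("", "0")] <- NA; x }
  df$father <- norm(df$father); df$mother <- norm(df$mother)
  df$genotype <- norm(df$genotype)
  if (anyDuplicated(df$id)) stop("duplicate individual id(s)")
  for (p in c(df$father, df$mother)) {
    if (!is.na(p) && !(p %in% df$id))
      stop("parent '", p, "' is not in the pedigree")
  }
  if (!all(df$phenotype %in% c("positive", "negative", "unknown")))
    stop("phenotype must be positive/negative/unknown")
  if (!all(is.na(df$genotype) | df$genotype %in% c("+/+", "+/-", "-/-")))
    stop("genotype must be +/+, +/-, -/- or NA")
  bad <- !is.na(df$genotype) &
    ((df$genotype == "-/-" & df$phenotype == "positive") |
       (df$genotype != "-/-" & df$phenotype == "negative"))
  if (any(bad))
    stop("known genotype contradicts phenotype for: ",
         paste(df$id[bad], collapse = ", "))
  # topological sort; also detects cycles
  order_ids <- character(0)
  placed <- stats::setNames(rep(FALSE, nrow(df)), df$id)
  remaining <- df$id
  while (length(remaining)) {
    ready <- vapply(remaining, function(i) {
      r <- df[df$id == i, ]
      (is.na(r$father) || placed[[r$father]]) &&
        (is.na(r$mother) || placed[[r$mother]])
    }, logical(1))
    if (!any(ready)) stop("pedigree contains a cycle (individual is its ",
                          "own ancestor)")
    order_ids <- c(order_ids, remaining[ready])
    placed[remaining[ready]] <- TRUE
    remaining <- remaining[!ready]
  }
  df <- df[match(order_ids, df$id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Read a pedigree TSV
#'
#' Expects columns `id`, `father`, `mother`, `sex`, `phenotype`, optionally
#' `genotype` and `evidence`; see [as_pedigree()].
#'
#' @param path TSV path.
#' @return A `pedigree` object.
#' @export
read_pedigree <- function(path) {
  as_pedigree(utils::read.delim(path, stringsAsFactors = FALSE,
                                na.strings = c("NA", "")))
}

# Genotypes encoded as the number of + alleles: 0 = -/-, 1 = +/-, 2 = +/+.
geno_label <- c(`0` = "-/-", `1` = "+/-", `2` = "+/+")
geno_code <- c(`-/-` = 0L, `+/-` = 1L, `+/+` = 2L)

# Per-individual allowed genotype codes given phenotype + known genotype.
allowed_genotypes <- function(phenotype, genotype) {
  lapply(seq_along(phenotype), function(i) {
    g <- if (!is.na(genotype[i])) geno_code[[genotype[i]]] else
      switch(phenotype[i], positive = c(1L, 2L), negative = 0L,
             unknown = 0:2)
    g
  })
}

# Alleles transmissible by a genotype code.
transmissible <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)

# Depth-first satisfiability over topologically sorted individuals.
# allowed: list of integer vectors, aligned with ped rows (parents first).
ped_satisfiable <- function(ped, allowed) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  assign_rec <- function(i, genos) {
    if (i > n) return(TRUE)
    for (g in allowed[[i]]) {
      ok <- TRUE
      f <- fa[i]; m <- mo[i]
      if (!is.na(f) || !is.na(m)) {
        pa <- if (!is.na(f)) transmissible[[as.character(genos[f])]] else 0:1
        pb <- if (!is.na(m)) transmissible[[as.character(genos[m])]] else 0:1
        ok <- any(outer(pa, pb, `+`) == g)
      }
      if (ok) {
        genos[i] <- g
        if (assign_rec(i + 1L, genos)) return(TRUE)
      }
    }
    FALSE
  }
  assign_rec(1L, integer(n))
}

check_size <- function(ped) {
  if (nrow(ped) > 25L)
    stop("pedigree has ", nrow(ped), " members; exhaustive genotype ",
         "enumeration is limited to 25 — decompose the family first")
}

#' Mendelian consistency of a dominant fusion marker
#'
#' Searches for any genotype assignment consistent with the observed
#' phenotypes (and known genotypes, if present) under biallelic Mendelian
#' transmission with no de-novo events.  If none exists, returns all
#' minimal-cardinality sets of individuals whose phenotype must be flipped
#' to restore consistency.
#'
#' @param ped A [as_pedigree()] object (at most 25 members).
#' @param max_flips Largest flip-set cardinality searched (default 3).
#' @return List of class `mendelian_check` with elements `consistent`
#'   (logical) and `flip_sets` (list of character vectors; empty when
#'   consistent).
#' @export
mendelian_check <- function(ped, max_flips = 3L) {
  ped <- as_pedigree(ped)
  check_size(ped)
  allowed <- allowed_genotypes(ped$phenotype, ped$genotype)
  if (ped_satisfiable(ped, allowed))
    return(structure(list(consistent = TRUE, flip_sets = list()),
                     class = "mendelian_check"))
  observed <- which(ped$phenotype != "unknown")
  flip <- function(ph) ifelse(ph == "positive", "negative", "positive")
  flip_sets <- list()
  for (size in seq_len(min(max_flips, length(observed)))) {
    sets <- utils::combn(observed, size, simplify = FALSE)
    for (s in sets) {
      ph <- ped$phenotype
      ph[s] <- flip(ph[s])
      gt <- ped$genotype
      gt[s] <- NA  # a flipped observation invalidates its genotype call too
      if (ped_satisfiable(ped, allowed_genotypes(ph, gt)))
        flip_sets[[length(flip_sets) + 1L]] <- sort(ped$id[s])
    }
    if (length(flip_sets)) break
  }
  structure(list(consistent = FALSE, flip_sets = flip_sets),
            class = "mendelian_check")
}

#' @export
print.mendelian_check <- function(x, ...) {
  if (x$consistent) {
    cat("pedigree is Mendelian-consistent for a dominant marker\n")
  } else {
    cat("pedigree is INCONSISTENT; minimal phenotype flip set(s):\n")
    for (s in x$flip_sets) cat("  {", paste(s, collapse = ", "), "}\n")
  }
  invisible(x)
}

#' Constraint-based genotype inference for a dominant marker
#'
#' For each individual, reports the set of genotypes realizable in at least
#' one consistent assignment, the forced genotype when that set is a
#' singleton, and a maximum-likelihood genotype for ambiguous individuals:
#' for parents, by the offspring-transmission likelihood (product over
#' children of the probability of each child's phenotype given this
#' parent's genotype and the co-parent's genotype, the co-parent taken at
#' its forced genotype or marginalized under the prior); for individuals
#' without offspring, by the population prior implied by carrier frequency
#' `prior` (Hardy-Weinberg).  `lr` is the likelihood ratio of the best over
#' the second-best genotype.
#'
#' @param ped A consistent [as_pedigree()] object.
#' @param prior Population carrier frequency of the fusion allele
#'   (default 0.289).
#' @return Data frame of class `genotype_assignment`: `id`, `possible`,
#'   `forced`, `ml_genotype`, `lr`.
#' @export
infer_genotypes <- function(ped, prior = 0.289) {
  ped <- as_pedigree(ped)
  check_size(ped)
  allowed <- allowed_genotypes(ped$phenotype, ped$genotype)
  if (!ped_satisfiable(ped, allowed))
    stop("pedigree is not Mendelian-consistent; run mendelian_check() ",
         "to locate the violation")
  n <- nrow(ped)
  q <- 1 - sqrt(1 - prior)  # allele frequency from carrier frequency
  hw <- c(`0` = (1 - q)^2, `1` = 2 * q * (1 - q), `2` = q^2)

  possible <- vector("list", n)
  for (i in seq_len(n)) {
    possible[[i]] <- Filter(function(g) {
      al <- allowed
      al[[i]] <- g
      ped_satisfiable(ped, al)
    }, allowed[[i]])
  }

  # P(child phenotype | parent genotypes a, b), b possibly marginalized
  child_lik <- function(phen, ga, gb_w) {
    # gb_w: named weights over co-parent genotype codes
    sapply_sum <- 0
    for (gb in as.integer(names(gb_w))) {
      pa <- mean(transmissible[[as.character(ga)]])
      pb <- mean(transmissible[[as.character(gb)]])
      p_pos <- 1 - (1 - pa) * (1 - pb)
      p <- switch(phen, positive = p_pos, negative = 1 - p_pos, unknown = 1)
      sapply_sum <- sapply_sum + gb_w[[as.character(gb)]] * p
    }
    sapply_sum
  }

  ml <- character(n); lr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    poss <- possible[[i]]
    if (length(poss) <= 1L) { ml[i] <- geno_label[as.character(poss[1L])]
      next }
    kids <- which(ped$father == ped$id[i] | ped$mother == ped$id[i])
    lik <- stats::setNames(numeric(length(poss)), as.character(poss))
    if (length(kids)) {
      for (g in poss) {
        l <- 1
        for (kid in kids) {
          other <- if (identical(ped$father[kid], ped$id[i]))
            ped$mother[kid] else ped$father[kid]
          if (!is.na(other)) {
            oi <- match(other, ped$id)
            op <- possible[[oi]]
            if (length(op) == 1L) {
              w <- stats::setNames(1, as.character(op))
            } else {
              w <- hw[as.character(op)] / sum(hw[as.character(op)])
            }
          } else w <- hw / sum(hw)
          l <- l * child_lik(ped$phenotype[kid], g, w)
        }
        lik[as.character(g)] <- l
      }
    } else {
      lik[] <- hw[names(lik)]
    }
    ord <- order(-lik)
    ml[i] <- geno_label[names(lik)[ord[1L]]]
    lr[i] <- lik[ord[1L]] / lik[ord[2L]]
  }

  out <- data.frame(
    id = ped$id,
    possible = vapply(possible, function(p)
      paste(geno_label[as.character(p)], collapse = "|"), character(1)),
    forced = vapply(possible, function(p)
      if (length(p) == 1L) geno_label[[as.character(p)]] else "ambiguous",
      character(1)),
    ml_genotype = ml,
    lr = lr,
    stringsAsFactors = FALSE
  )
  class(out) <- c("genotype_assignment", "data.frame")
  out
}

#' @export
print.genotype_assignment <- function(x, ...) {
  cat("genotype inference (dominant presence marker)\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Scan for sample swaps restoring Mendelian consistency
#'
#' For an inconsistent pedigree, tests every unordered pair of individuals
#' with differing observed phenotypes: a pair is a candidate iff exchanging
#' their phenotypes (known genotype calls stay with the individual) makes
#' the pedigree consistent — the signature of two samples having been mixed
#' up.
#'
#' @param ped A [as_pedigree()] object.
#' @return Data frame with columns `id1`, `id2`, deterministically sorted;
#'   empty when the pedigree is already consistent or no single swap
#'   explains the inconsistency.  Known genotype calls travel with the
#'   swapped samples.
#' @export
swap_scan <- function(ped) {
  ped <- as_pedigree(ped)
  check_size(ped)
  empty <- data.frame(id1 = character(0), id2 = character(0),
                      stringsAsFactors = FALSE)
  if (ped_satisfiable(ped, allowed_genotypes(ped$phenotype, ped$genotype)))
    return(empty)
  n <- nrow(ped)
  found <- list()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (ped$phenotype[i] == ped$phenotype[j]) next
    ph <- ped$phenotype
    ph[c(i, j)] <- ph[c(j, i)]
    gt <- ped$genotype
    gt[c(i, j)] <- gt[c(j, i)]  # the whole sample moves, zygosity call too
    if (ped_satisfiable(ped, allowed_genotypes(ph, gt)))
      found[[length(found) + 1L]] <- sort(c(ped$id[i], ped$id[j]))
  }
  if (length(found) == 0L) return(empty)
  out <- unique(data.frame(id1 = vapply(found, `[`, "", 1L),
                           id2 = vapply(found, `[`, "", 2L),
                           stringsAsFactors = FALSE))
  out <- out[order(out$id1, out$id2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' A bundled synthetic three-generation pedigree
#'
#' Seventeen members — four grandparents, two parents, eleven children —
#' emulating a deeply sequenced reference family in which one child's
#' RNA sample was mixed up with a grandfather's: as measured, the
#' grandfather types positive and one son negative, while WGS zygosity pins
#' the mother as homozygous-positive, making the negative son a Mendelian
#' violation.  Swapping the two samples restores consistency.
#'
#' @param corrected Return the corrected pedigree (swap applied, genotype
#'   pin removed) instead of the as-measured one.
#' @return A `pedigree` object.
#' @export
example_pedigree <- function(corrected = FALSE) {
  kid_ids <- sprintf("CH%02d", 1:11)
  df <- data.frame(
    id = c("GF1", "GM1", "GF2", "GM2", "FA", "MO", kid_ids),
    father = c(NA, NA, NA, NA, "GF1", "GF2", rep("FA", 11L)),
    mother = c(NA, NA, NA, NA, "GM1", "GM2", rep("MO", 11L)),
    sex = c("M", "F", "M", "F", "M", "F",
            rep(c("M", "F"), length.out = 11L)),
    phenotype = c("positive", "positive", "positive", "positive",
                  "negative", "positive",
                  c("negative", rep("positive", 10L))),
    genotype = c(NA, NA, NA, NA, NA, "+/+", rep(NA, 11L)),
    evidence = c(rep("RNA", 5L), "both", rep("RNA", 11L)),
    stringsAsFactors = FALSE
  )
  if (corrected) {
    df$phenotype[df$id == "GF1"] <- "negative"
    df$phenotype[df$id == "CH01"] <- "positive"
    df$genotype <- NA_character_
  }
  as_pedigree(df)
}
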