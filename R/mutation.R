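#' Mutation model configuration
#'
#' Neutral mutations are overlaid on finished genealogies, one independent
#' genealogy per locus ("unlinked loci"). Two models:
#'
#' * `"infinite_sites"`: mutations fall on each branch as a Poisson process
#'   with rate `mu * seq_length` per unit branch length and every mutation
#'   hits a fresh site, yielding binary haplotypes;
#' * `"k2p"`: Kimura two-parameter nucleotide substitution along each branch,
#'   with transition/transversion rate ratio `kappa` and the root sequence
#'   drawn from the stationary (uniform) base distribution.
#'
#' The rate convention: `mu` is the expected number of substitutions per site
#' per unit (model) time, i.e. the K2P rate matrix is normalized so that
#' transitions occur at rate `kappa * mu / (kappa + 2)` and each of the two
#' transversions at rate `mu / (kappa + 2)`.
#'
#' @param model `"k2p"` or `"infinite_sites"`.
#' @param mu Mutation rate per site per unit time, >= 0.
#' @param kappa Transition/transversion rate ratio (> 0; `kappa = 1` reduces
#'   to Jukes-Cantor). K2P only.
#' @param seq_length Sites per locus (>= 1).
#' @param n_loci Number of independent loci (>= 1), each with its own
#'   genealogy.
#' @return A list of class `slfv_mutation_config`.
#' @export
mutation_config <- function(model = c("k2p", "infinite_sites"), mu,
                            kappa = 3, seq_length = 1000L, n_loci = 1L) {
  model <- match.arg(model)
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0)
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa > 0)
  stopifnot(seq_length >= 1, n_loci >= 1)
  structure(
    list(model = model, mu = mu, kappa = kappa,
         seq_length = as.integer(seq_length), n_loci = as.integer(n_loci)),
    class = "slfv_mutation_config"
  )
}

k2p_rates <- function(mu, kappa) {
  beta <- mu / (kappa + 2)
  list(alpha = kappa * beta, beta = beta)
}

#' Kimura two-parameter rate and transition-probability matrices
#'
#' `k2p_rate_matrix()` returns the instantaneous rate matrix Q (rows sum to
#' zero) for bases ordered A, C, G, T, normalized so the total substitution
#' rate per site is `mu`. `k2p_transition_matrix()` returns the closed-form
#' substitution probability matrix `expm(Q t)`: at `t = 0` the identity, and
#' for large `mu * t` every entry tends to the stationary 1/4.
#'
#' @param t Elapsed time (>= 0).
#' @param mu Substitution rate per site per unit time.
#' @param kappa Transition/transversion rate ratio.
#' @return A 4x4 numeric matrix with dimnames A, C, G, T.
#' @examples
#' k2p_transition_matrix(0.1, mu = 1, kappa = 3)
#' @export
k2p_rate_matrix <- function(mu, kappa) {
  r <- k2p_rates(mu, kappa)
  b <- c("A", "C", "G", "T")
  Q <- matrix(r$beta, 4, 4, dimnames = list(b, b))
  Q["A", "G"] <- Q["G", "A"] <- Q["C", "T"] <- Q["T", "C"] <- r$alpha
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' @rdname k2p_rate_matrix
#' @export
k2p_transition_matrix <- function(t, mu, kappa) {
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop("`t` must be a single non-negative time", call. = FALSE)
  }
  r <- k2p_rates(mu, kappa)
  e1 <- exp(-4 * r$beta * t)
  e2 <- exp(-2 * (r$alpha + r$beta) * t)
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1
  b <- c("A", "C", "G", "T")
  P <- matrix(p_tv, 4, 4, dimnames = list(b, b))
  P["A", "G"] <- P["G", "A"] <- P["C", "T"] <- P["T", "C"] <- p_ts
  diag(P) <- p_same
  P
}

# parent-before-child node order: internal nodes are created in increasing
# backward time, so every parent has a larger node id than its children
check_coalesced <- function(g) {
  if (!inherits(g, "slfv_genealogy")) stop("need an slfv_genealogy", call. = FALSE)
  if (!g$coalesced) {
    stop(structure(
      class = c("slfv_not_coalesced", "error", "condition"),
      list(message = "genealogy did not coalesce; refusing to overlay mutations",
           call = NULL)
    ))
  }
  invisible(g)
}

new_alignment <- function(mat, ids, model, locus = 1L) {
  rownames(mat) <- ids
  structure(mat, class = c("slfv_alignment", class(mat)),
            model = model, locus = locus)
}

#' @export
print.slfv_alignment <- function(x, ...) {
  cat(sprintf(
    "<slfv_alignment> %s locus %s: %d sequences x %d sites, %d segregating\n",
    attr(x, "model"), attr(x, "locus"), nrow(x), ncol(x), n_segregating(x)
  ))
  invisible(x)
}

n_segregating <- function(aln) {
  sum(matrixStats_colAnyDiff(aln))
}

matrixStats_colAnyDiff <- function(m) {
  if (nrow(m) == 1L) return(rep(FALSE, ncol(m)))
  colSums(m != m[rep(1L, nrow(m)), , drop = FALSE]) > 0
}

#' Overlay neutral mutations on a genealogy
#'
#' Simulates one locus of genetic data down a coalesced genealogy under the
#' chosen mutation model (see [mutation_config()]). Branch lengths are in the
#' simulator's model time, so `mu` is per site per unit model time.
#'
#' @param g A coalesced [simulate_genealogy()] result.
#' @param config A [mutation_config()].
#' @param locus Locus id recorded on the alignment.
#' @return An `slfv_alignment`: a matrix with one row per sampled individual
#'   (rownames = sample ids) and `seq_length` columns; characters A/C/G/T for
#'   `"k2p"`, integers 0/1 (ancestral/derived) for `"infinite_sites"`.
#' @export
overlay_mutations <- function(g, config, locus = 1L) {
  check_coalesced(g)
  nodes <- g$nodes
  n <- g$n_leaves
  L <- config$seq_length
  ids <- nodes$label[seq_len(n)]

  if (config$model == "k2p") {
    states <- matrix(NA_integer_, nrow(nodes), L)
    root <- nrow(nodes)
    states[root, ] <- sample.int(4L, L, replace = TRUE)
    if (nrow(nodes) > 1L) {
      for (v in seq(nrow(nodes) - 1L, 1L)) {
        p <- nodes$parent[v]
        bl <- nodes$time[p] - nodes$time[v]
        P <- k2p_transition_matrix(bl, config$mu, config$kappa)
        ps <- states[p, ]
        cs <- integer(L)
        for (s in 1:4) {
          at <- which(ps == s)
          if (length(at)) cs[at] <- sample.int(4L, length(at), replace = TRUE,
                                               prob = P[s, ])
        }
        states[v, ] <- cs
      }
    }
    mat <- matrix(c("A", "C", "G", "T")[states[seq_len(n), , drop = FALSE]],
                  n, L)
    return(new_alignment(mat, ids, "k2p", locus))
  }

  # infinite sites: Poisson mutations per branch, each at a fresh site,
  # marking all leaves descended from the mutated branch
  kids <- split(nodes$node, factor(nodes$parent, levels = nodes$node))
  leaves_below <- vector("list", nrow(nodes))
  for (v in seq_len(nrow(nodes))) {
    ch <- kids[[v]]
    leaves_below[[v]] <- if (!length(ch)) v else
      unlist(leaves_below[ch], use.names = FALSE)
  }
  non_root <- which(!is.na(nodes$parent))
  bl <- nodes$time[nodes$parent[non_root]] - nodes$time[non_root]
  n_mut <- stats::rpois(length(non_root), config$mu * L * bl)
  total <- sum(n_mut)
  if (total > L) {
    stop("more mutations (", total, ") than sites (", L,
         "); lower mu or lengthen the locus", call. = FALSE)
  }
  mat <- matrix(0L, n, L)
  if (total > 0L) {
    sites <- sample.int(L, total)
    s0 <- 0L
    for (i in seq_along(non_root)) {
      if (n_mut[i] == 0L) next
      carriers <- leaves_below[[non_root[i]]]
      cols <- sites[(s0 + 1L):(s0 + n_mut[i])]
      mat[carriers, cols] <- 1L
      s0 <- s0 + n_mut[i]
    }
  }
  new_alignment(mat, ids, "infinite_sites", locus)
}

#' Simulate a multilocus spatial dataset
#'
#' Draws `n_loci` independent SLFV genealogies for the same sampled
#' individuals and overlays one locus of mutations on each — the "unlinked
#' loci" design. Any locus whose genealogy fails to coalesce within
#' `max_events` aborts the dataset with a classed error
#' (`slfv_not_coalesced`) rather than returning partial data.
#'
#' @inheritParams simulate_genealogy
#' @param config A [mutation_config()].
#' @param keep_genealogies Keep the per-locus genealogies on the result
#'   (default `FALSE` to save memory in large reference tables).
#' @return An `slfv_dataset`: list with `alignments` (list of
#'   `slfv_alignment`), `sheet`, `config` and optionally `genealogies`.
#' @export
simulate_dataset <- function(sheet, landscape, kernel, config,
                             max_events = 1e7, keep_genealogies = FALSE,
                             engine = "auto") {
  sheet <- validate_sample_sheet(sheet, landscape)
  alns <- vector("list", config$n_loci)
  gens <- if (keep_genealogies) vector("list", config$n_loci)
  for (l in seq_len(config$n_loci)) {
    g <- simulate_genealogy(sheet, landscape, kernel, max_events, engine)
    check_coalesced(g)
    alns[[l]] <- overlay_mutations(g, config, locus = l)
    if (keep_genealogies) gens[[l]] <- g
  }
  structure(
    list(alignments = alns, sheet = sheet, config = config,
         genealogies = gens),
    class = "slfv_dataset"
  )
}

#' @export
print.slfv_dataset <- function(x, ...) {
  cat(sprintf(
    "<slfv_dataset> %d individuals, %d locus/loci x %d sites (%s)\n",
    nrow(x$sheet), x$config$n_loci, x$config$seq_length, x$config$model
  ))
  invisible(x)
}

#' FASTA and site-matrix input/output for simulated loci
#'
#' Nucleotide alignments are written as FASTA wrapped at 80 columns with
#' record ids equal to the individual ids; binary (infinite-sites)
#' alignments as a tab-separated 0/1 site matrix with an `id` column.
#' `write_dataset()` writes one file per locus
#' (`<prefix>.locus<k>.fa` / `.sites.tsv`).
#'
#' @param aln An `slfv_alignment`.
#' @param path Output file.
#' @return The path (writers, invisibly) or an `slfv_alignment` (readers).
#' @export
write_locus_fasta <- function(aln, path) {
  if (attr(aln, "model") != "k2p") {
    stop("FASTA output is for nucleotide alignments; use write_site_matrix()",
         call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    s <- paste(aln[i, ], collapse = "")
    starts <- seq(1L, nchar(s), by = 80L)
    writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname write_locus_fasta
#' @export
read_locus_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  mat <- toupper(do.call(rbind, lapply(as.character(dna), identity)))
  new_alignment(mat, names(dna), "k2p")
}

#' @rdname write_locus_fasta
#' @export
write_site_matrix <- function(aln, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(aln)), .name_repair = "minimal")
  names(df) <- paste0("s", seq_len(ncol(aln)))
  df <- dplyr::bind_cols(tibble::tibble(id = rownames(aln)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_locus_fasta
#' @export
read_site_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_integer()
  ))
  mat <- as.matrix(df[, -1, drop = FALSE])
  dimnames(mat) <- NULL
  new_alignment(mat, df$id, "infinite_sites")
}

#' @rdname write_locus_fasta
#' @param ds An `slfv_dataset`.
#' @param prefix Output path prefix.
#' @export
write_dataset <- function(ds, prefix) {
  for (l in seq_along(ds$alignments)) {
    a <- ds$alignments[[l]]
    if (attr(a, "model") == "k2p") {
      write_locus_fasta(a, sprintf("%s.locus%d.fa", prefix, l))
    } else {
      write_site_matrix(a, sprintf("%s.locus%d.sites.tsv", prefix, l))
    }
  }
  invisible(prefix)
}
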