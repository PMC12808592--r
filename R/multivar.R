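#' Build a gene x trait phenotype profile matrix
#'
#' Two normalization regimes feed the multivariate layer. `"zdiff"` rows
#' are z-scored differences from the sex-matched control, `(m - c) / S`
#' with `S` the across-knockdown SD — control rows are exactly zero and the
#' matrix asks "how does each knockdown deviate from its own sex's
#' baseline". `"absolute"` rows are the raw genotype means with male and
#' female rows pooled and each trait z-normalized across the pool — this
#' preserves sex differences in trait magnitude, so male and female rows
#' separate, and cross-sex distances are meaningful.
#'
#' @param table tidy replicate-level phenotype table (`genotype`, `sex`,
#'   `trait`, `value`).
#' @param mode `"zdiff"` or `"absolute"`.
#' @param controlLabel control genotype label.
#' @param minKnockdowns SD stability guard passed to [callHits()]
#'   internals (zdiff mode).
#' @return a [ProfileMatrix-class]; rows are named `<gene>|<sex>`, control
#'   rows included. Zero-variance traits are dropped with a warning.
#' @export
buildProfileMatrix <- function(table, mode = c("zdiff", "absolute"),
                               controlLabel = "control",
                               minKnockdowns = 10L) {
  mode <- match.arg(mode)
  mm <- phenotypeMeans(table)
  traits <- unique(mm$trait)
  genos <- unique(mm$genotype)
  sexes <- unique(mm$sex)
  rowInfo <- expand.grid(gene = genos, sex = sexes,
                         stringsAsFactors = FALSE)
  rowInfo$isControl <- rowInfo$gene == controlLabel
  rn <- paste(rowInfo$gene, rowInfo$sex, sep = "|")
  vals <- matrix(NA_real_, nrow(rowInfo), length(traits),
                 dimnames = list(rn, traits))
  for (k in seq_len(nrow(mm))) {
    vals[paste(mm$genotype[k], mm$sex[k], sep = "|"), mm$trait[k]] <-
      mm$mean[k]
  }
  if (mode == "zdiff") {
    ht <- callHits(table, controlLabel = controlLabel,
                   minKnockdowns = minKnockdowns)
    sds <- ht@traitSD
    for (tr in traits) for (sx in sexes) {
      sel <- rowInfo$sex == sx
      ctl <- vals[paste(controlLabel, sx, sep = "|"), tr]
      s <- sds$sd[sds$trait == tr & sds$sex == sx]
      vals[sel, tr] <- (vals[sel, tr] - ctl) / s
    }
  } else {
    keep <- rep(TRUE, length(traits))
    for (ti in seq_along(traits)) {
      v <- vals[, ti]
      if (sd(v, na.rm = TRUE) == 0 || all(is.na(v))) {
        keep[ti] <- FALSE
        next
      }
      vals[, ti] <- (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
    }
    if (!all(keep)) {
      warning(sprintf("dropping zero-variance trait(s): %s",
                      paste(traits[!keep], collapse = ", ")))
      vals <- vals[, keep, drop = FALSE]
    }
  }
  new("ProfileMatrix", values = vals, mode = mode, rowInfo = rowInfo)
}

#' Hierarchical clustering of phenotype profiles
#'
#' Distance is `1 - r_s` (Spearman rank correlation, pairwise-complete)
#' between profiles, merged by average linkage (UPGMA) — so any strictly
#' increasing transform of a profile leaves the dendrogram unchanged.
#' Constant profiles, whose rank correlation is undefined, are dropped
#' with a warning.
#'
#' @param pm a [ProfileMatrix-class] or numeric matrix.
#' @param axis cluster `"rows"` (profiles) or `"columns"` (traits).
#' @return list with `hclust` (stats::hclust object), `order` (leaf
#'   labels in dendrogram order), `cophenetic` (dist), `dropped` (labels
#'   of constant profiles).
#' @export
hclusterProfiles <- function(pm, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- if (is(pm, "ProfileMatrix")) profileValues(pm) else pm
  if (axis == "columns") m <- t(m)
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  cons <- apply(m, 1, function(x) sd(x, na.rm = TRUE) == 0 | all(is.na(x)))
  dropped <- rownames(m)[cons]
  if (length(dropped)) {
    warning(sprintf("dropping constant profile(s): %s",
                    paste(dropped, collapse = ", ")))
    m <- m[!cons, , drop = FALSE]
  }
  if (nrow(m) < 3L) stop("need >= 3 non-constant items to cluster")
  rs <- pairwiseSpearman(m, minShared = 3L)$r
  d <- as.dist(1 - rs)
  hc <- hclust(d, method = "average")
  list(hclust = hc, order = rownames(m)[hc$order],
       cophenetic = cophenetic(hc), dropped = dropped)
}

#' Centered-SVD principal component analysis of phenotype profiles
#'
#' Columns are centered (z-normalization is done upstream by the profile
#' matrix) and decomposed by singular value decomposition; scores are
#' `U * Sigma`. Component signs are fixed deterministically by forcing the
#' largest-magnitude loading of each component positive, so embeddings are
#' reproducible bit for bit. Missing values are median-imputed per trait
#' with a message.
#'
#' @param pm a [ProfileMatrix-class] or numeric matrix.
#' @param nComponents number of components to keep (default: full rank).
#' @return a [PhenoEmbedding-class].
#' @export
phenotypePCA <- function(pm, nComponents = NULL) {
  m <- if (is(pm, "ProfileMatrix")) profileValues(pm) else as.matrix(pm)
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  rowInfo <- if (is(pm, "ProfileMatrix")) profileRowInfo(pm)
  else data.frame(gene = rownames(m), sex = NA_character_,
                  isControl = FALSE)
  if (nrow(m) < 3L || ncol(m) < 2L)
    stop("PCA needs >= 3 rows and >= 2 columns")
  if (anyNA(m)) {
    message("median-imputing missing values per trait before PCA")
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      m[nas, j] <- median(m[, j], na.rm = TRUE)
    }
  }
  mc <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(mc)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  if (is.null(nComponents)) nComponents <- rank
  if (nComponents > rank) {
    warning(sprintf("requested %d components but rank is %d; truncating",
                    nComponents, rank))
    nComponents <- rank
  }
  flip <- vapply(seq_len(rank), function(k) {
    l <- sv$v[, k]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(rank), drop = FALSE] %*%
                    diag(sv$d[seq_len(rank)], rank), 2, flip, `*`)
  loadings <- sweep(sv$v[, seq_len(rank), drop = FALSE], 2, flip, `*`)
  ve <- sv$d[seq_len(rank)]^2 / sum(sv$d^2)
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(rank)))
  dimnames(loadings) <- list(colnames(m), paste0("PC", seq_len(rank)))
  new("PhenoEmbedding",
      scores = scores[, seq_len(nComponents), drop = FALSE],
      loadings = loadings[, seq_len(nComponents), drop = FALSE],
      varExplained = ve[seq_len(nComponents)], rowInfo = rowInfo)
}

#' Distances to a reference profile in the PC1 x PC2 plane
#'
#' Euclidean distance from every row of the embedding to the named
#' reference row (typically the opposite-sex control), ranked ascending —
#' the smaller the distance, the more the knockdown's phenotypic profile
#' resembles the reference state.
#'
#' @param embedding a [PhenoEmbedding-class].
#' @param reference row name of the reference (e.g. `"control|male"`).
#' @param rows optional row names to restrict the ranking to (e.g. female
#'   knockdowns only).
#' @param fullSpace use all components instead of PC1 x PC2.
#' @return data.frame ordered by distance: `row`, `distance`, `rank`.
#' @export
pcaDistances <- function(embedding, reference, rows = NULL,
                         fullSpace = FALSE) {
  sc <- pcaScores(embedding)
  if (!reference %in% rownames(sc))
    stop(sprintf("reference row '%s' not in the embedding", reference))
  use <- if (fullSpace) seq_len(ncol(sc)) else seq_len(min(2L, ncol(sc)))
  ref <- sc[reference, use]
  if (is.null(rows)) rows <- rownames(sc)
  d <- sqrt(colSums((t(sc[rows, use, drop = FALSE]) - ref)^2))
  out <- data.frame(row = rows, distance = d)
  out <- out[order(out$distance), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Male-female pair distances per genotype in the PC1 x PC2 plane
#'
#' For each genotype present in both sexes, the Euclidean distance between
#' its female and male rows — small distances mark knockdowns that erase
#' the sex difference, large ones knockdowns that widen it.
#'
#' @param embedding a [PhenoEmbedding-class] built from `<gene>|<sex>`
#'   rows.
#' @param fullSpace use all components instead of PC1 x PC2.
#' @return data.frame ordered by distance: `gene`, `distance`, `rank`.
#' @export
sexPairDistances <- function(embedding, fullSpace = FALSE) {
  sc <- pcaScores(embedding)
  info <- profileRowInfo(embedding)
  use <- if (fullSpace) seq_len(ncol(sc)) else seq_len(min(2L, ncol(sc)))
  genes <- intersect(info$gene[info$sex == "female"],
                     info$gene[info$sex == "male"])
  d <- vapply(genes, function(g) {
    f <- sc[paste(g, "female", sep = "|"), use]
    m <- sc[paste(g, "male", sep = "|"), use]
    sqrt(sum((f - m)^2))
  }, numeric(1))
  out <- data.frame(gene = genes, distance = unname(d))
  out <- out[order(out$distance), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
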