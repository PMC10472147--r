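#' Read and validate a pedigree
#'
#' Reads a three-column pedigree (animal, sire, dam; unknown parents coded
#' `"0"`, `NA` or empty), auto-inserts founders that appear only as parents,
#' checks consistency, and renumbers all animals in topological order so that
#' every parent's index precedes its offspring's index. The topological sort is
#' deterministic: ties are broken by order of first appearance in the input.
#'
#' @param source path to a headered CSV with columns `animal,sire,dam`, or a
#'   data frame with those columns (extra columns are ignored).
#' @return An object of class `pedigree`: a data frame with character columns
#'   `animal`, `sire`, `dam` (`"0"` = unknown) and integer columns `sire_i`,
#'   `dam_i` (0 = unknown), one row per animal, rows in renumbered order.
#'   Row `i` is the animal with index `i`.
#' @details Duplicate records with identical parent triples are collapsed; an
#'   animal recorded with two different parent sets is an error, as is any
#'   cycle (an animal among its own ancestors).
#' @export
read_pedigree <- function(source) {
  df <- if (is.character(source)) {
    utils::read.csv(source, colClasses = "character", strip.white = TRUE)
  } else {
    as.data.frame(source)
  }
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree source must have columns animal, sire, dam")
  }
  an <- as.character(df$animal)
  si <- as.character(df$sire)
  da <- as.character(df$dam)
  norm_unknown <- function(x) {
    x[is.na(x) | x == "" | x == "0" | x == "NA"] <- "0"
    x
  }
  si <- norm_unknown(si)
  da <- norm_unknown(da)
  if (any(is.na(an) | an == "" | an == "0")) {
    stop("animal ids must be non-missing and not '0'")
  }
  if (any(an == si | an == da)) {
    bad <- an[an == si | an == da][1]
    stop("animal '", bad, "' is recorded as its own parent")
  }

  # deduplicate identical triples; conflicting duplicates are an error
  key <- paste(an, si, da, sep = "\r")
  keep <- !duplicated(key)
  an <- an[keep]; si <- si[keep]; da <- da[keep]
  if (anyDuplicated(an)) {
    bad <- an[duplicated(an)][1]
    stop("animal '", bad, "' is listed with two different parent sets")
  }

  # founders referenced only as parents, in order of first appearance
  parents <- unique(c(si, da))
  parents <- setdiff(parents, c("0", an))
  if (length(parents)) {
    an <- c(an, parents)
    si <- c(si, rep("0", length(parents)))
    da <- c(da, rep("0", length(parents)))
  }

  n <- length(an)
  idx <- seq_len(n)
  names(idx) <- an
  si_i <- ifelse(si == "0", 0L, idx[si])
  da_i <- ifelse(da == "0", 0L, idx[da])

  # Kahn topological sort, ties broken by input order (min-heap on input rank)
  indeg <- (si_i > 0L) + (da_i > 0L)
  children <- vector("list", n)
  for (r in seq_len(n)) {
    for (p in unique(c(si_i[r], da_i[r]))) {
      if (p > 0L) children[[p]] <- c(children[[p]], r)
    }
  }
  order_out <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    nxt <- ready[which.min(ready)] # smallest input rank first
    ready <- setdiff(ready, nxt)
    order_out <- c(order_out, nxt)
    for (ch in children[[nxt]]) {
      indeg[ch] <- indeg[ch] - sum(c(si_i[ch], da_i[ch]) == nxt)
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order_out) < n) {
    cyc <- an[setdiff(seq_len(n), order_out)]
    stop("pedigree contains a cycle involving: ", paste(cyc, collapse = ", "))
  }

  rank_new <- integer(n)
  rank_new[order_out] <- seq_len(n)
  ped <- data.frame(
    animal = an[order_out],
    sire = si[order_out],
    dam = da[order_out],
    sire_i = ifelse(si_i[order_out] > 0L, rank_new[pmax(si_i[order_out], 1L)],
                    0L),
    dam_i = ifelse(da_i[order_out] > 0L, rank_new[pmax(da_i[order_out], 1L)],
                   0L),
    stringsAsFactors = FALSE
  )
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree> ", nrow(x), " animals, ",
      sum(x$sire_i == 0L & x$dam_i == 0L), " founders\n", sep = "")
  utils::str(as.data.frame(utils::head(x, 6)))
  invisible(x)
}

#' Number of animals in a pedigree
#' @param ped a `pedigree`
#' @return integer count
#' @export
n_animals <- function(ped) nrow(ped)

ped_index <- function(ped, ids) {
  i <- match(ids, ped$animal)
  if (anyNA(i)) {
    stop("ids not in pedigree: ", paste(ids[is.na(i)], collapse = ", "))
  }
  i
}

#' Write the renumbered pedigree cross-reference
#'
#' Emits `animal,sire,dam,index` in renumbered (topological) order.
#'
#' @param ped a `pedigree`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_pedigree_xref <- function(ped, path) {
  out <- data.frame(animal = ped$animal, sire = ped$sire, dam = ped$dam,
                    index = seq_len(nrow(ped)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Inbreeding coefficients by Meuwissen-Luo
#'
#' Computes `F_i` for every animal by the ancestor-tracing algorithm: for each
#' animal the L-vector of expected genetic contributions is accumulated from
#' descendant to ancestor and combined with each ancestor's Mendelian-sampling
#' variance coefficient `D_j`. Unknown parents are base (non-inbred, unrelated)
#' animals.
#'
#' @param ped a `pedigree`
#' @return numeric vector of inbreeding coefficients in pedigree order
#' @export
inbreeding <- function(ped) {
  n <- nrow(ped)
  s <- ped$sire_i
  d <- ped$dam_i
  F <- numeric(n)
  Dcoef <- function(i) {
    fs <- if (s[i] > 0L) F[s[i]] else -1
    fd <- if (d[i] > 0L) F[d[i]] else -1
    0.5 - 0.25 * (fs + fd)
  }
  D <- numeric(n)
  for (i in seq_len(n)) {
    D[i] <- Dcoef(i)
    if (s[i] == 0L || d[i] == 0L) {
      F[i] <- 0
      next
    }
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * D[j]
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * L[j]
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * L[j]
    }
    F[i] <- aii - 1
  }
  names(F) <- ped$animal
  F
}
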