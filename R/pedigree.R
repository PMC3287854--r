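#' Generate a set of extended pedigrees
#'
#' Builds `n_families` non-inbred families totalling exactly `n_total`
#' members and `n_founders` founders. Each family descends from a single
#' founding couple; blood-line children take married-in spouses (counted as
#' founders) in the middle generations, and the last generation is unmarried.
#' With four generations the most distant relatives are second cousins. The
#' defaults (8 families, 697 members, 202 founders, 4 generations) reproduce
#' the aggregate structure of the family sampling design; the exact published
#' pedigree shapes are not public, so only these aggregate counts are matched.
#'
#' Sibship sizes are balanced deterministically to hit the requested totals;
#' the seed only affects the sexes of blood-line children (spouse sexes are
#' forced by their partner).
#'
#' @param n_families Number of families (default 8).
#' @param n_total Total individuals across families (default 697).
#' @param n_founders Total founders, i.e. members with no parents in the
#'   pedigree (default 202).
#' @param n_generations Generations per family, 2 to 4 (default 4).
#' @param seed Integer seed.
#' @return A `pedigree`: data frame with columns `person_id`, `family_id`,
#'   `father_id`, `mother_id` (`NA` for founders), `sex` (`"M"`/`"F"`),
#'   `generation`, `founder`; rows in parent-before-child order.
#' @examples
#' ped <- generate_pedigree_set(1, 14, 6, 3, seed = 1)
#' sum(ped$founder)
#' @export
generate_pedigree_set <- function(n_families = 8L, n_total = 697L,
                                  n_founders = 202L, n_generations = 4L,
                                  seed = 1L) {
  if (n_founders > n_total)
    stop("infeasible pedigree request: n_founders > n_total")
  if (n_founders < 2L * n_families)
    stop("infeasible pedigree request: need at least 2 founders per family")
  if (!n_generations %in% 2:4)
    stop("n_generations must be 2, 3 or 4")
  set.seed(seed)
  totals <- balanced_split(n_total, n_families)
  founders <- balanced_split(n_founders, n_families)
  fams <- lapply(seq_len(n_families), function(f)
    build_family(sprintf("FAM%02d", f), totals[f], founders[f], n_generations))
  ped <- do.call(rbind, fams)
  rownames(ped) <- NULL
  ped$founder <- is.na(ped$father_id) & is.na(ped$mother_id)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

balanced_split <- function(total, k) {
  out <- rep(total %/% k, k)
  extra <- total %% k
  if (extra > 0L) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  out
}

# n children split over k units, near-equal, deterministic
sibship_sizes <- function(n, k) {
  if (k == 0L) return(integer(0))
  balanced_split(n, k)
}

build_family <- function(fam_id, n_total, n_founders, n_gen) {
  spouses <- n_founders - 2L
  children_total <- n_total - n_founders
  if (n_gen == 2L) {
    if (spouses != 0L)
      stop("infeasible pedigree request: a 2-generation family has exactly 2 founders")
    if (children_total < 1L)
      stop("infeasible pedigree request: a family needs at least one child")
    m2 <- 0L; m3 <- 0L
    c2 <- children_total; c3 <- 0L; c4 <- 0L
  } else if (n_gen == 3L) {
    if (spouses < 1L)
      stop("infeasible pedigree request: 3 generations require married-in spouses")
    m2 <- spouses; m3 <- 0L
    c2 <- m2
    c3 <- children_total - c2
    c4 <- 0L
    if (c3 < m2)
      stop("infeasible pedigree request: not enough members for grandchildren")
  } else {
    if (spouses < 2L)
      stop("infeasible pedigree request: 4 generations require spouses in two generations")
    c4 <- children_total - spouses            # c2 + c3 == spouses by design
    if (c4 < 1L)
      stop("infeasible pedigree request: not enough members for 4 generations")
    m3 <- max(1L, min(spouses - 1L, c4, round(spouses * 0.78)))
    m2 <- spouses - m3
    c2 <- m2
    c3 <- m3
  }

  nid <- 0L
  new_id <- function() {
    nid <<- nid + 1L
    sprintf("%s_%03d", fam_id, nid)
  }
  rows <- list()
  add <- function(id, fa, mo, sex, gen) {
    rows[[length(rows) + 1L]] <<- data.frame(
      person_id = id, family_id = fam_id,
      father_id = fa, mother_id = mo, sex = sex, generation = gen,
      stringsAsFactors = FALSE)
  }
  rand_sex <- function(n) c("M", "F")[stats::rbinom(n, 1L, 0.5) + 1L]

  g1f <- new_id(); g1m <- new_id()
  add(g1f, NA, NA, "M", 1L); add(g1m, NA, NA, "F", 1L)

  make_children <- function(couples, counts, gen) {
    kids <- character(0)
    for (j in seq_along(counts)) {
      if (counts[j] == 0L) next
      sex <- rand_sex(counts[j])
      for (s in sex) {
        id <- new_id()
        add(id, couples[[j]][["father"]], couples[[j]][["mother"]], s, gen)
        kids <- c(kids, id)
      }
    }
    kids
  }
  marry <- function(ids, n_married, gen) {
    couples <- list()
    sexes <- vapply(ids, function(i) rows_sex(i), "")
    for (j in seq_len(n_married)) {
      child <- ids[j]
      child_sex <- sexes[j]
      sp <- new_id()
      add(sp, NA, NA, if (child_sex == "M") "F" else "M", gen)
      couples[[j]] <- if (child_sex == "M")
        c(father = child, mother = sp) else c(father = sp, mother = child)
    }
    couples
  }
  rows_sex <- function(id) {
    for (r in rev(rows)) if (r$person_id == id) return(r$sex)
    stop("unknown id")
  }

  g2 <- make_children(list(c(father = g1f, mother = g1m)),
                      sibship_sizes(c2, 1L), 2L)
  if (n_gen >= 3L && m2 > 0L) {
    couples2 <- marry(g2, m2, 2L)
    g3 <- make_children(couples2, sibship_sizes(c3, m2), 3L)
    if (n_gen == 4L && m3 > 0L) {
      couples3 <- marry(g3, m3, 3L)
      make_children(couples3, sibship_sizes(c4, m3), 4L)
    }
  }
  do.call(rbind, rows)
}

#' Founder flags of a pedigree
#' @param ped A `pedigree`.
#' @return Logical vector: `TRUE` for members with no parents in the pedigree.
#' @export
is_founder <- function(ped) is.na(ped$father_id) & is.na(ped$mother_id)

topological_order <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  pos <- match(ped$father_id, ped$person_id)
  mos <- match(ped$mother_id, ped$person_id)
  placed <- rep(FALSE, n)
  parent_ok <- function(p) is.na(p) | placed[ifelse(is.na(p), 1L, p)]
  order <- integer(0)
  while (length(order) < n) {
    ready <- !placed & parent_ok(pos) & parent_ok(mos)
    if (!any(ready)) stop("pedigree contains a cycle or missing parent")
    order <- c(order, idx[ready])
    placed[ready] <- TRUE
  }
  order
}

validate_pedigree <- function(ped) {
  stopifnot(all(c("person_id", "family_id", "father_id", "mother_id", "sex")
                %in% names(ped)))
  if (anyDuplicated(ped$person_id)) stop("duplicate person ids in pedigree")
  half <- xor(is.na(ped$father_id), is.na(ped$mother_id))
  if (any(half)) stop("every non-founder must have both parents present")
  fa <- ped$father_id[!is.na(ped$father_id)]
  mo <- ped$mother_id[!is.na(ped$mother_id)]
  if (!all(fa %in% ped$person_id) || !all(mo %in% ped$person_id))
    stop("parent ids must refer to pedigree members")
  sex <- stats::setNames(ped$sex, ped$person_id)
  if (any(sex[fa] != "M")) stop("all fathers must be male")
  if (any(sex[mo] != "F")) stop("all mothers must be female")
  invisible(topological_order(ped))
}

#' Kinship matrix of a pedigree
#'
#' Computes kinship coefficients by the standard recursive algorithm, walking
#' the pedigree from founders to leaves: for a non-founder `i` with parents
#' `(f, m)` and any earlier `j`, `phi(i, j) = (phi(f, j) + phi(m, j)) / 2` and
#' `phi(i, i) = 1/2 + phi(f, m) / 2`. Founders are treated as unrelated and
#' non-inbred, so parent-offspring pairs get 1/4, full sibs 1/4, first
#' cousins 1/16, second cousins 1/64. Expected pairwise allele sharing is
#' `2 * phi`, the quantity the polygenic model and Haseman-Elston regression
#' use.
#'
#' @param ped A `pedigree`.
#' @return Symmetric numeric matrix with person ids as dimnames.
#' @examples
#' ped <- generate_pedigree_set(1, 14, 6, 3, seed = 1)
#' kin <- kinship(ped)
#' @export
kinship <- function(ped) {
  ord <- validate_pedigree(ped)
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$person_id, ped$person_id))
  fa <- match(ped$father_id, ped$person_id)
  mo <- match(ped$mother_id, ped$person_id)
  done <- integer(0)
  for (i in ord) {
    if (is.na(fa[i])) {
      phi[i, i] <- 0.5
    } else {
      if (length(done)) {
        v <- 0.5 * (phi[fa[i], done] + phi[mo[i], done])
        phi[i, done] <- v
        phi[done, i] <- v
      }
      phi[i, i] <- 0.5 + 0.5 * phi[fa[i], mo[i]]
    }
    done <- c(done, i)
  }
  phi
}

#' Write a pedigree in PED/FAM format
#'
#' Six whitespace-delimited columns: family, individual, father, mother
#' (0 = missing), sex (1 = male, 2 = female), phenotype placeholder (0).
#'
#' @param ped A `pedigree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  out <- data.frame(
    fid = ped$family_id, iid = ped$person_id,
    fat = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mot = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = ifelse(ped$sex == "M", 1L, 2L),
    pheno = 0L)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PED/FAM file
#'
#' @param path Path to a 6-column PED/FAM file (0 = missing parent).
#' @return A `pedigree` (generation recomputed as depth below founders).
#' @export
read_ped <- function(path) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("fid", "iid", "fat", "mot", "sex",
                                       "pheno"))
  ped <- data.frame(
    person_id = as.character(d$iid), family_id = as.character(d$fid),
    father_id = ifelse(d$fat == "0", NA_character_, as.character(d$fat)),
    mother_id = ifelse(d$mot == "0", NA_character_, as.character(d$mot)),
    sex = ifelse(d$sex == 1L, "M", "F"),
    stringsAsFactors = FALSE)
  # generation = 1 + longest ancestral path
  gen <- rep(NA_integer_, nrow(ped))
  fa <- match(ped$father_id, ped$person_id)
  mo <- match(ped$mother_id, ped$person_id)
  ord <- topological_order(ped)
  for (i in ord) {
    gen[i] <- if (is.na(fa[i])) 1L else max(gen[fa[i]], gen[mo[i]]) + 1L
  }
  ped$generation <- gen
  ped$founder <- is.na(ped$father_id) & is.na(ped$mother_id)
  class(ped) <- c("pedigree", "data.frame")
  ped
}
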