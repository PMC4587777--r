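#' Pedigree construction and validation
#'
#' A `pedigree` is a data frame with one row per individual and columns
#' `id`, `father`, `mother` (both `NA` for founders), `sex`
#' (`"male"`/`"female"`), `affected` (logical) and `family` (label used to
#' group nuclear families for per-family analyses). Invariants enforced:
#' parents are both present or both absent, fathers are male and mothers
#' female, parent references resolve within the pedigree, and the structure
#' is acyclic (no individual is its own ancestor).
#'
#' @name pedigree
NULL

new_pedigree <- function(df, template = "custom", carrier = NULL) {
  ped <- validate_pedigree(df)
  attr(ped, "template") <- template
  attr(ped, "carrier") <- carrier
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Validate a pedigree table
#'
#' @param df data frame with columns `id`, `father`, `mother`, `sex`,
#'   `affected` and optionally `family`.
#' @return the validated `pedigree` (rows in input order).
#' @export
validate_pedigree <- function(df) {
  need <- c("id", "father", "mother", "sex", "affected")
  if (!all(need %in% names(df)))
    stop("pedigree table must have columns: ", paste(need, collapse = ", "))
  df$id <- as.character(df$id)
  df$father <- as.character(df$father)
  df$mother <- as.character(df$mother)
  df$father[df$father %in% c("", "0")] <- NA_character_
  df$mother[df$mother %in% c("", "0")] <- NA_character_
  if (!"family" %in% names(df)) df$family <- "FAM1"
  if (anyDuplicated(df$id))
    stop("duplicated individual id: ", df$id[duplicated(df$id)][1])
  for (i in seq_len(nrow(df))) {
    id <- df$id[i]; fa <- df$father[i]; mo <- df$mother[i]
    if (is.na(fa) != is.na(mo))
      stop("individual ", id, ": father and mother must both be set or both absent")
    if (!is.na(fa)) {
      if (fa == id || mo == id)
        stop("individual ", id, " is listed as its own parent")
      if (!fa %in% df$id)
        stop("individual ", id, ": father ", fa, " not in pedigree")
      if (!mo %in% df$id)
        stop("individual ", id, ": mother ", mo, " not in pedigree")
      if (df$sex[match(fa, df$id)] != "male")
        stop("individual ", id, ": father ", fa, " is not male")
      if (df$sex[match(mo, df$id)] != "female")
        stop("individual ", id, ": mother ", mo, " is not female")
    }
  }
  if (!any(is.na(df$father))) stop("pedigree has no founder")
  ord <- topo_order(df)  # errors on cycles, naming an offending individual
  attr(df, "topo") <- ord
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

# Kahn topological order over parent->child edges; cycle => error
topo_order <- function(df) {
  ids <- df$id
  indeg <- ifelse(is.na(df$father), 0L, 2L)
  ord <- character(0)
  ready <- ids[indeg == 0L]
  remaining <- indeg
  names(remaining) <- ids
  while (length(ready)) {
    x <- ready[1]; ready <- ready[-1]
    ord <- c(ord, x)
    kids <- ids[!is.na(df$father) & (df$father == x | df$mother == x)]
    for (k in kids) {
      remaining[k] <- remaining[k] - 1L
      if (remaining[k] == 0L) ready <- c(ready, k)
    }
  }
  if (length(ord) != length(ids)) {
    bad <- setdiff(ids, ord)
    stop("pedigree contains an ancestry cycle involving individual ", bad[1])
  }
  ord
}

#' @export
founders <- function(pedigree) pedigree$id[is.na(pedigree$father)]

#' @export
affected_ids <- function(pedigree) pedigree$id[pedigree$affected]

ped_row <- function(id, father, mother, sex, affected, family) {
  data.frame(id = id, father = father, mother = mother, sex = sex,
             affected = affected, family = family, stringsAsFactors = FALSE)
}

#' Build a pedigree from a named template
#'
#' Templates mirror the family structures of autozygosity-mapping studies
#' of consanguineous families:
#' * `first_cousin`: an affected child whose parents are first cousins
#'   (one shared grandparental couple); the child's inbreeding coefficient
#'   is 1/16.
#' * `double_first_cousin`: an affected child whose parents are first
#'   cousins through both the paternal and the maternal line (two shared
#'   grandparental couples); F = 1/8.
#' * `two_family_founder`: two nuclear families (a first-cousin family and
#'   a double-first-cousin family) joined through one common ancestral
#'   couple that carries the founder haplotype; each family has one
#'   affected child.
#' * `custom`: validate and return `members` as supplied.
#'
#' Templates attach a *carrier chain* attribute: the founder-haplotype
#' label and the ordered parent-to-child transmissions an autosomal
#' recessive founder mutation must follow so that every affected child is
#' homozygous for it, plus the unaffected siblings that must not be. It is
#' consumed by [drop_genes()] when simulating ascertained families.
#'
#' @param template template name (see above).
#' @param members for `template = "custom"`, a pedigree data frame.
#' @param include_sib add one unaffected sibling per affected child
#'   (default `TRUE`); siblings make segregation analysis informative.
#' @return a validated `pedigree`.
#' @examples
#' ped <- build_pedigree("first_cousin")
#' inbreeding_coefficient(ped, affected_ids(ped)[1])  # 0.0625
#' @export
build_pedigree <- function(template = c("first_cousin", "double_first_cousin",
                                        "two_family_founder", "custom"),
                           members = NULL, include_sib = TRUE) {
  template <- match.arg(template)
  if (template == "custom") {
    if (is.null(members)) stop("template 'custom' requires a members table")
    return(new_pedigree(members, template = "custom"))
  }
  fc <- function(pre, fam) {
    # shared grandparental couple GP_F x GP_M; their children U1, U2 marry in
    rbind(
      ped_row(paste0(pre, c("GP_F", "GP_M")), NA, NA, c("male", "female"), FALSE, fam),
      ped_row(paste0(pre, c("U1", "U2")), paste0(pre, "GP_F"), paste0(pre, "GP_M"),
              c("male", "female"), FALSE, fam),
      ped_row(paste0(pre, c("U1_SP", "U2_SP")), NA, NA, c("female", "male"), FALSE, fam),
      ped_row(paste0(pre, "FA"), paste0(pre, "U1"), paste0(pre, "U1_SP"), "male", FALSE, fam),
      ped_row(paste0(pre, "MO"), paste0(pre, "U2_SP"), paste0(pre, "U2"), "female", FALSE, fam),
      ped_row(paste0(pre, "P1"), paste0(pre, "FA"), paste0(pre, "MO"), "female", TRUE, fam)
    )
  }
  # both U1 and U2 must receive the allele from GP_F for the child to be
  # homozygous identical by descent
  fc_chain <- function(pre) {
    data.frame(parent = paste0(pre, c("GP_F", "GP_F", "U1", "U2", "FA", "MO")),
               child  = paste0(pre, c("U1", "U2", "FA", "MO", "P1", "P1")),
               stringsAsFactors = FALSE)
  }

  dfc <- function(pre, fam) {
    # two grandparental couples GA, GB; sib pairs A1/A2 and B1/B2 intermarry
    rbind(
      ped_row(paste0(pre, c("GA_F", "GA_M", "GB_F", "GB_M")), NA, NA,
              c("male", "female", "male", "female"), FALSE, fam),
      ped_row(paste0(pre, c("A1", "A2")), paste0(pre, "GA_F"), paste0(pre, "GA_M"),
              c("male", "female"), FALSE, fam),
      ped_row(paste0(pre, c("B1", "B2")), paste0(pre, "GB_F"), paste0(pre, "GB_M"),
              c("female", "male"), FALSE, fam),
      ped_row(paste0(pre, "FA"), paste0(pre, "A1"), paste0(pre, "B1"), "male", FALSE, fam),
      ped_row(paste0(pre, "MO"), paste0(pre, "B2"), paste0(pre, "A2"), "female", FALSE, fam),
      ped_row(paste0(pre, "P1"), paste0(pre, "FA"), paste0(pre, "MO"), "female", TRUE, fam)
    )
  }
  dfc_chain <- function(pre) {
    data.frame(parent = paste0(pre, c("GA_F", "GA_F", "A1", "A2", "FA", "MO")),
               child  = paste0(pre, c("A1", "A2", "FA", "MO", "P1", "P1")),
               stringsAsFactors = FALSE)
  }

  add_sib <- function(df, pre, fam) {
    rbind(df, ped_row(paste0(pre, "S1"), paste0(pre, "FA"), paste0(pre, "MO"),
                      "male", FALSE, fam))
  }

  if (template == "first_cousin") {
    df <- fc("", "FAM1")
    if (include_sib) df <- add_sib(df, "", "FAM1")
    carrier <- list(hap = "GP_F.1", chain = fc_chain(""),
                    avoid_hom = if (include_sib) "S1" else character(0))
    return(new_pedigree(df, template, carrier))
  }
  if (template == "double_first_cousin") {
    df <- dfc("", "FAM1")
    if (include_sib) df <- add_sib(df, "", "FAM1")
    carrier <- list(hap = "GA_F.1", chain = dfc_chain(""),
                    avoid_hom = if (include_sib) "S1" else character(0))
    return(new_pedigree(df, template, carrier))
  }
  # two_family_founder: ancestral couple ANC_F x ANC_M; child X1 founds the
  # grandparental couple of a first-cousin family, child X2 that of a
  # double-first-cousin family
  anc <- ped_row(c("ANC_F", "ANC_M"), NA, NA, c("male", "female"), FALSE, "ANC")
  f1 <- fc("F1_", "FAM1")
  f1$father[f1$id == "F1_GP_F"] <- "ANC_F"; f1$mother[f1$id == "F1_GP_F"] <- "ANC_M"
  f2 <- dfc("F2_", "FAM2")
  f2$father[f2$id == "F2_GA_M"] <- "ANC_F"; f2$mother[f2$id == "F2_GA_M"] <- "ANC_M"
  # F2_GA_M is female -> she descends from the ancestral couple
  df <- rbind(anc, f1, f2)
  if (include_sib) { df <- add_sib(df, "F1_", "FAM1"); df <- add_sib(df, "F2_", "FAM2") }
  chain <- rbind(
    data.frame(parent = c("ANC_F", "ANC_F"), child = c("F1_GP_F", "F2_GA_M"),
               stringsAsFactors = FALSE),
    fc_chain("F1_"),
    within(dfc_chain("F2_"), {
      parent[parent == "F2_GA_F"] <- "F2_GA_M"  # allele enters family 2 via F2_GA_M
    })
  )
  carrier <- list(hap = "ANC_F.1", chain = chain,
                  avoid_hom = if (include_sib) c("F1_S1", "F2_S1") else character(0))
  new_pedigree(df, template, carrier)
}

#' Wright's inbreeding coefficient by path counting
#'
#' Computes F, the probability that the two alleles of `individual` at a
#' random autosomal locus are identical by descent, as the sum over all
#' distinct ancestral paths joining the father and the mother through a
#' common ancestor A of \eqn{(1/2)^{L+1} (1 + F_A)}, where L is the number
#' of meioses on the path and \eqn{F_A} the (recursively computed)
#' inbreeding coefficient of A. The two branches of a path may share no
#' individual other than A. Founders are assumed non-inbred and mutually
#' unrelated.
#'
#' @param pedigree a [pedigree].
#' @param individual individual id.
#' @return F in `[0, 1]`; 1/16 for first-cousin offspring, 1/8 for
#'   double-first-cousin offspring.
#' @export
inbreeding_coefficient <- function(pedigree, individual) {
  i <- match(individual, pedigree$id)
  if (is.na(i)) stop("unknown individual id: ", individual)
  fa <- pedigree$father[i]; mo <- pedigree$mother[i]
  if (is.na(fa)) return(0)
  memo <- new.env(parent = emptyenv())
  path_f(pedigree, fa, mo, memo)
}

# all ancestor paths from id upward; each path is the id sequence ending at
# the ancestor (a path of length 1 is the individual itself)
ancestor_paths <- function(ped, id) {
  i <- match(id, ped$id)
  paths <- list(id)
  if (!is.na(ped$father[i])) {
    for (p in c(ped$father[i], ped$mother[i]))
      paths <- c(paths, lapply(ancestor_paths(ped, p), function(pp) c(id, pp)))
  }
  paths
}

path_f <- function(ped, fa, mo, memo) {
  key <- paste(fa, mo)
  if (!is.null(memo[[key]])) return(memo[[key]])
  pf <- ancestor_paths(ped, fa)
  pm <- ancestor_paths(ped, mo)
  total <- 0
  for (a in pf) for (b in pm) {
    A <- a[length(a)]
    if (A != b[length(b)]) next
    # branches must be disjoint except at the common ancestor A
    if (length(intersect(a[-length(a)], b[-length(b)])) > 0) next
    L <- (length(a) - 1) + (length(b) - 1)
    FA <- {
      ai <- match(A, ped$id)
      if (is.na(ped$father[ai])) 0 else path_f(ped, ped$father[ai], ped$mother[ai], memo)
    }
    total <- total + (1 / 2)^(L + 1) * (1 + FA)
  }
  memo[[key]] <- total
  total
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree (%s): %d individuals, %d founder(s), %d affected\n",
              attr(x, "template") %||% "custom", nrow(x), length(founders(x)),
              sum(x$affected)))
  print.data.frame(x, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
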