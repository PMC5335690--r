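# Hand-built synthetic micro-fixtures exercising the worked examples:
# exemplification of a higher-taxon tip, pruning of taxonomy-only taxa,
# the two-subproblem decomposition, and the broken-taxon attachment rule.

# Taxonomy: Life(1) = (ABCD(2) = (A(3)=(a1,a2), B(4)=(b1,b2), C(5)=(c1),
#                                 D(6)=(d1)),
#                      E(7) = (E1,E2), F(8) = (F1,F2))
# uids: a1=31 a2=32 b1=41 b2=42 c1=51 d1=61 E1=71 E2=72 F1=81 F2=82
micro_taxonomy <- function() {
  rec <- function(uid, parent, name, rank) {
    data.frame(uid = uid, parent_uid = parent, name = name, rank = rank,
               flags = "")
  }
  taxonomy(rbind(
    rec(1L, NA, "Life", "no rank"),
    rec(2L, 1L, "ABCD", "order"),
    rec(7L, 1L, "E", "genus"), rec(8L, 1L, "F", "genus"),
    rec(3L, 2L, "A", "genus"), rec(4L, 2L, "B", "genus"),
    rec(5L, 2L, "C", "genus"), rec(6L, 2L, "D", "genus"),
    rec(31L, 3L, "a1", "species"), rec(32L, 3L, "a2", "species"),
    rec(41L, 4L, "b1", "species"), rec(42L, 4L, "b2", "species"),
    rec(51L, 5L, "c1", "species"), rec(61L, 6L, "d1", "species"),
    rec(71L, 7L, "E1", "species"), rec(72L, 7L, "E2", "species"),
    rec(81L, 8L, "F1", "species"), rec(82L, 8L, "F2", "species")))
}

# tree1 samples a1, b1, c1, the higher taxon E, and F1; tree2 lies entirely
# inside ABCD and contests both A and B (interleaving their species), so
# ABCD and the root are the only decomposition points.
micro_trees <- function() {
  list(tree1 = parse_newick("((ott31,(ott41,ott51)),(ott7,ott81));"),
       tree2 = parse_newick("((ott31,ott41),(ott32,ott42));"))
}

micro_synthesis <- function() {
  run_synthesis(list(taxonomy = micro_taxonomy(), trees = micro_trees(),
                     prune_flags = character(0)))
}

# Broken-taxon fixture: taxonomy N = (R = (R1..R6), X = (x1), Y = (y1));
# the grafted solution interleaves R1 with x1, breaking R, and leaves
# R4, R5, R6 unsampled.
broken_taxonomy <- function() {
  rec <- function(uid, parent, name) {
    data.frame(uid = uid, parent_uid = parent, name = name, rank = "",
               flags = "")
  }
  taxonomy(rbind(
    rec(1L, NA, "N"), rec(2L, 1L, "R"), rec(3L, 1L, "X"), rec(4L, 1L, "Y"),
    rec(21L, 2L, "R1"), rec(22L, 2L, "R2"), rec(23L, 2L, "R3"),
    rec(24L, 2L, "R4"), rec(25L, 2L, "R5"), rec(26L, 2L, "R6"),
    rec(31L, 3L, "x1"), rec(41L, 4L, "y1")))
}

broken_grafted <- function() {
  g <- parse_newick("(((ott21,ott31),(ott22,ott23)),ott41)ott1;")
  g
}
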