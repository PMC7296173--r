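#include <Rcpp.h>
using namespace Rcpp;

// Clip amplitude peaks narrower than kappa in phase.
//
// Iterates over peaks of r left to right. For each peak an inclusive index
// range (a, b) is expanded greedily towards the larger neighbouring value
// while both ends descend. A range that reaches phase width
// phi[b] - phi[a] >= kappa is clipped to its running minimum m. A range
// whose right end hits a trough (next value ascends) is clipped to m and
// pushed for later merging; when a later peak's left end hits a trough and
// a touching range sits on top of the stack, the two are merged (m
// combines their minima, so interior valleys are accounted for) and the
// merged range continues to expand. A left trough with no touching range
// means the left neighbour is an already-clipped mesa at least kappa wide,
// which supplies the missing phase width at no cost to m, so the range is
// clipped in place. Remaining stacked ranges are clipped at the end.
// Runs in O(n): each sample enters a range once and merges only pop.
// [[Rcpp::export(name = ".mesaclip_kernel")]]
NumericVector mesaclip_kernel(NumericVector r_in, NumericVector phi, double kappa) {
  const int n = r_in.size();
  NumericVector r = clone(r_in);
  if (n <= 1 || kappa <= 0) return r;

  std::vector<int> stack_a, stack_b;
  std::vector<double> stack_m;

  auto clip = [&](int a, int b, double m) {
    for (int i = a; i <= b; ++i)
      if (r[i] > m) r[i] = m;
  };

  // peaks: first index of each maximal flat run that is a local maximum
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n - 1 && r[j + 1] == r[i]) ++j;
    bool left_ok = (i == 0) || (r[i - 1] < r[i]);
    bool right_ok = (j == n - 1) || (r[j + 1] < r[i]);
    if (left_ok && right_ok) {
      int a = i, b = i;
      double m = r[i];
      for (;;) {
        if (phi[b] - phi[a] >= kappa) {
          clip(a, b, m);
          break;
        }
        bool ascL = a > 0 && r[a - 1] > r[a];
        bool ascR = b < n - 1 && r[b + 1] > r[b];
        bool canL = a > 0 && !ascL;
        bool canR = b < n - 1 && !ascR;
        if (ascR) { // trough at the right end: clip and defer on the stack
          clip(a, b, m);
          stack_a.push_back(a);
          stack_b.push_back(b);
          stack_m.push_back(m);
          break;
        }
        if (ascL) {
          if (!stack_a.empty() && stack_b.back() >= a - 1) {
            // merge with the touching range on top of the stack
            a = std::min(a, stack_a.back());
            m = std::min(m, stack_m.back());
            stack_a.pop_back();
            stack_b.pop_back();
            stack_m.pop_back();
            continue;
          }
          // left neighbour is a clipped mesa >= kappa wide: width satisfied
          clip(a, b, m);
          break;
        }
        if (canL && canR) {
          if (r[a - 1] > r[b + 1]) {
            --a;
            if (r[a] < m) m = r[a];
          } else { // tie expands right
            ++b;
            if (r[b] < m) m = r[b];
          }
        } else if (canR) {
          ++b;
          if (r[b] < m) m = r[b];
        } else if (canL) {
          --a;
          if (r[a] < m) m = r[a];
        } else {
          // both ends at array boundaries with width < kappa
          clip(a, b, m);
          stack_a.push_back(a);
          stack_b.push_back(b);
          stack_m.push_back(m);
          break;
        }
      }
    }
    i = j + 1;
  }

  while (!stack_a.empty()) {
    clip(stack_a.back(), stack_b.back(), stack_m.back());
    stack_a.pop_back();
    stack_b.pop_back();
    stack_m.pop_back();
  }
  return r;
}
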