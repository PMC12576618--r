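#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Suffix array by prefix-doubling over cyclic shifts (counting sort per
// round, O(n log n)).  Requires the terminal invariant (unique smallest
// symbol at the last position) so that cyclic-shift order equals suffix
// order; validated on the R side.
// [[Rcpp::export]]
IntegerVector sa_int_cpp(IntegerVector s_) {
    const int n = s_.size();
    if (n == 0) return IntegerVector(0);
    if (n == 1) return IntegerVector::create(0);

    std::vector<int> s(s_.begin(), s_.end());
    int mx = *std::max_element(s.begin(), s.end());
    int alpha = mx + 1;

    std::vector<int> p(n), c(n), pn(n), cn(n), cnt(std::max(alpha, n), 0);

    for (int i = 0; i < n; i++) cnt[s[i]]++;
    for (int i = 1; i < alpha; i++) cnt[i] += cnt[i - 1];
    for (int i = 0; i < n; i++) p[--cnt[s[i]]] = i;
    c[p[0]] = 0;
    int classes = 1;
    for (int i = 1; i < n; i++) {
        if (s[p[i]] != s[p[i - 1]]) classes++;
        c[p[i]] = classes - 1;
    }

    for (int h = 1; h < n; h <<= 1) {
        for (int i = 0; i < n; i++) {
            pn[i] = p[i] - h;
            if (pn[i] < 0) pn[i] += n;
        }
        std::fill(cnt.begin(), cnt.begin() + classes, 0);
        for (int i = 0; i < n; i++) cnt[c[pn[i]]]++;
        for (int i = 1; i < classes; i++) cnt[i] += cnt[i - 1];
        for (int i = n - 1; i >= 0; i--) p[--cnt[c[pn[i]]]] = pn[i];
        cn[p[0]] = 0;
        classes = 1;
        for (int i = 1; i < n; i++) {
            int a1 = c[p[i]], b1 = c[(p[i] + h) % n];
            int a0 = c[p[i - 1]], b0 = c[(p[i - 1] + h) % n];
            if (a1 != a0 || b1 != b0) classes++;
            cn[p[i]] = classes - 1;
        }
        std::swap(c, cn);
        if (classes == n) break;
    }
    return IntegerVector(p.begin(), p.end());
}

// Karp-Rabin fingerprints of every length-w window of x (byte values),
// polynomial rolling hash: f(r) = sum r[i] * base^(w-1-i) mod m.
// mod must be < 2^31 so all intermediates fit in uint64.
// [[Rcpp::export]]
IntegerVector kr_windows_cpp(IntegerVector x, int w, double base_, double mod_) {
    const int n = x.size();
    const uint64_t b = (uint64_t)base_, m = (uint64_t)mod_;
    if (w > n) return IntegerVector(0);
    const int k = n - w + 1;
    IntegerVector out(k);
    uint64_t h = 0, bw = 1;  // bw = base^(w-1) mod m
    for (int i = 0; i < w - 1; i++) bw = (bw * b) % m;
    for (int i = 0; i < w; i++) h = (h * b + (uint64_t)x[i]) % m;
    out[0] = (int)h;
    for (int j = 1; j < k; j++) {
        uint64_t drop = ((uint64_t)x[j - 1] * bw) % m;
        h = (h + m - drop) % m;
        h = (h * b + (uint64_t)x[j + w - 1]) % m;
        out[j] = (int)h;
    }
    return out;
}

// Overlapping-occurrence count of pat in text by direct scan (test oracle).
// [[Rcpp::export]]
int naive_count_cpp(IntegerVector text, IntegerVector pat) {
    const int n = text.size(), m = pat.size();
    if (m == 0 || m > n) return 0;
    int cnt = 0;
    for (int i = 0; i + m <= n; i++) {
        int j = 0;
        while (j < m && text[i + j] == pat[j]) j++;
        if (j == m) cnt++;
    }
    return cnt;
}
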