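# Default synthetic food-supply specification: 1,370 products across the
# five studied categories (seven leaf codes), with category-typical
# truncated-normal nutrient distributions, log-normal (heavy-tailed)
# 12-month sales, and a per-category sales-quality bias linking sales to
# a continuous nutritional-quality index (negative Ofcom score). Negative
# bias = market leaders less healthy (breakfast cereals); positive bias =
# market leaders healthier (cheese).
version: "1"
seed: null            # must be supplied at generation time
categories:
  breakfast_cereals:
    count: 320
    nutrients:
      energy_kj:      {dist: normal, mean: 1600, sd: 150, min: 1100, max: 2000}
      total_fat_g:    {dist: lognormal, meanlog: 1.6, sdlog: 0.7, min: 0.5, max: 25}
      sat_fat_share:  {dist: uniform, min: 0.1, max: 0.5}
      total_sugars_g: {dist: normal, mean: 22, sd: 10, min: 1, max: 45}
      salt_g:         {dist: normal, mean: 0.7, sd: 0.4, min: 0, max: 2}
      fibre_g:        {dist: normal, mean: 6, sd: 3, min: 0.5, max: 15}
      protein_g:      {dist: normal, mean: 9, sd: 2, min: 4, max: 15}
    fvn:        {prob: 0.25, min: 5, max: 30}
    wholegrain: {prob: 0.40, min: 30, max: 100}
    sweetener_prob: 0.02
    sales: {meanlog: 7.6, sdlog: 1.2, bias: -0.6}
  pasta:
    count: 250
    nutrients:
      energy_kj:      {dist: normal, mean: 1520, sd: 60, min: 1350, max: 1700}
      total_fat_g:    {dist: normal, mean: 1.8, sd: 0.8, min: 0.2, max: 8}
      sat_fat_share:  {dist: uniform, min: 0.15, max: 0.35}
      total_sugars_g: {dist: normal, mean: 3, sd: 1.5, min: 0.1, max: 8}
      salt_g:         {dist: lognormal, meanlog: -3.0, sdlog: 1.0, min: 0, max: 0.8}
      fibre_g:        {dist: normal, mean: 3, sd: 1, min: 1, max: 6}
      protein_g:      {dist: normal, mean: 12.5, sd: 1.2, min: 9, max: 16}
    wholegrain: {prob: 0.30, min: 50, max: 100, fibre_mean: 7.5, fibre_sd: 1.2}
    sweetener_prob: 0.0
    sales: {meanlog: 7.6, sdlog: 1.2, bias: 0.3}
  cheese:
    count: 370
    nutrients:
      energy_kj:      {dist: normal, mean: 1350, sd: 280, min: 500, max: 1900}
      total_fat_g:    {dist: normal, mean: 27, sd: 7, min: 3, max: 40}
      sat_fat_share:  {dist: uniform, min: 0.60, max: 0.72}
      total_sugars_g: {dist: normal, mean: 1, sd: 1, min: 0, max: 5}
      salt_g:         {dist: normal, mean: 1.6, sd: 0.5, min: 0.1, max: 3.5}
      fibre_g:        {dist: constant, value: 0}
      protein_g:      {dist: normal, mean: 22, sd: 4, min: 10, max: 32}
      calcium_mg:     {dist: normal, mean: 700, sd: 150, min: 250, max: 1100}
    sweetener_prob: 0.0
    sales: {meanlog: 7.6, sdlog: 1.2, bias: 0.6}
  yoghurt_plain:
    count: 80
    nutrients:
      energy_kj:      {dist: normal, mean: 270, sd: 60, min: 150, max: 450}
      total_fat_g:    {dist: normal, mean: 3.3, sd: 1.4, min: 0.1, max: 10}
      sat_fat_share:  {dist: uniform, min: 0.60, max: 0.70}
      total_sugars_g: {dist: normal, mean: 4.8, sd: 0.8, min: 2.5, max: 7.5}
      salt_g:         {dist: normal, mean: 0.13, sd: 0.04, min: 0.02, max: 0.3}
      fibre_g:        {dist: constant, value: 0}
      protein_g:      {dist: normal, mean: 4.2, sd: 0.8, min: 2.8, max: 7}
    lactose_g: 4.7
    sweetener_prob: 0.02
    sales: {meanlog: 7.6, sdlog: 1.2, bias: 0.3}
  yoghurt_flavoured:
    count: 180
    nutrients:
      energy_kj:      {dist: normal, mean: 400, sd: 80, min: 220, max: 650}
      total_fat_g:    {dist: normal, mean: 2.8, sd: 1.3, min: 0.1, max: 9}
      sat_fat_share:  {dist: uniform, min: 0.60, max: 0.70}
      total_sugars_g: {dist: normal, mean: 12.5, sd: 3, min: 6, max: 22}
      salt_g:         {dist: normal, mean: 0.13, sd: 0.05, min: 0.02, max: 0.35}
      fibre_g:        {dist: normal, mean: 0.2, sd: 0.2, min: 0, max: 1}
      protein_g:      {dist: normal, mean: 3.6, sd: 0.8, min: 2.2, max: 6.5}
    lactose_g: 4.2
    sweetener_prob: 0.15
    sales: {meanlog: 7.6, sdlog: 1.2, bias: 0.3}
  yoghurt_drink_flavoured:
    count: 70
    nutrients:
      energy_kj:      {dist: normal, mean: 330, sd: 70, min: 180, max: 550}
      total_fat_g:    {dist: normal, mean: 1.5, sd: 1.0, min: 0.1, max: 5}
      sat_fat_share:  {dist: uniform, min: 0.60, max: 0.70}
      total_sugars_g: {dist: normal, mean: 11, sd: 3, min: 5, max: 20}
      salt_g:         {dist: normal, mean: 0.12, sd: 0.04, min: 0.02, max: 0.3}
      fibre_g:        {dist: constant, value: 0}
      protein_g:      {dist: normal, mean: 3.0, sd: 0.6, min: 1.8, max: 5}
    lactose_g: 3.8
    sweetener_prob: 0.20
    sales: {meanlog: 7.6, sdlog: 1.2, bias: 0.3}
  cooking_oil:
    count: 100
    nutrients:
      total_fat_g:    {dist: uniform, min: 91, max: 100}
      sat_fat_g:      {dist: uniform, min: 7, max: 92}    # capped at total fat
      total_sugars_g: {dist: constant, value: 0}
      salt_g:         {dist: constant, value: 0}
      fibre_g:        {dist: constant, value: 0}
      protein_g:      {dist: constant, value: 0}
    energy_from_fat_kj_per_g: 37
    sweetener_prob: 0.0
    sales: {meanlog: 7.6, sdlog: 1.2, bias: 0.3}
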